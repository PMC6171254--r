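test_that("case generation is deterministic given the seed", {
  c1 <- make_case(synth_case_config(seed = 99))
  c2 <- make_case(synth_case_config(seed = 99))
  expect_identical(c1$series$wss, c2$series$wss)
  expect_identical(c1$series$pressure, c2$series$pressure)
  expect_identical(c1$image, c2$image)
  c3 <- make_case(synth_case_config(seed = 100))
  expect_false(identical(c1$series$wss, c3$series$wss))
})

test_that("generated cases honor the planted-patch contract", {
  case <- make_case(synth_case_config(seed = 21))
  gt <- case$ground_truth
  expect_true(any(gt$twa_face_mask))
  expect_true(any(gt$twa_pixel_mask))
  expect_true(all(which(gt$twa_face_mask) %in% which(unclass(case$sac))))
  # more-dangerous annotation center lies inside the planted pixel mask
  ann <- gt$annotations$more_dangerous
  expect_true(gt$twa_pixel_mask[round(ann$cy) + 1, round(ann$cx) + 1])
  # image is valid 8-bit sRGB
  expect_true(is.integer(case$image))
  expect_true(all(case$image >= 0L & case$image <= 255L))
  # OSI of the generated series stays in range
  osi <- as.numeric(compute_osi(case$series))
  expect_true(all(osi >= 0 & osi <= 0.5))
})

test_that("reversal fraction drives OSI between its analytic limits", {
  flat <- rep(1, 32)
  cfg0 <- synth_case_config(seed = 1, reversal_fraction = 0,
                            wss_spatial_sd = 0, waveform = flat)
  osi0 <- as.numeric(compute_osi(make_case(cfg0, with_image = FALSE)$series))
  expect_lt(max(osi0), 1e-9)
  cfg5 <- synth_case_config(seed = 1, reversal_fraction = 0.5,
                            wss_spatial_sd = 0, waveform = flat)
  case5 <- make_case(cfg5, with_image = FALSE)
  osi5 <- as.numeric(compute_osi(case5$series))
  inside <- case5$ground_truth$twa_face_mask
  expect_equal(osi5[inside], rep(0.5, sum(inside)), tolerance = 1e-9)
  expect_lt(max(osi5[!inside]), 1e-9)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(synth_case_config(wss_deficit = 1.2), "wss_deficit")
  expect_error(synth_case_config(reversal_fraction = 0.7),
               "reversal_fraction")
  expect_error(synth_case_config(n_times = 4), "n_times")
  expect_error(synth_case_config(waveform = rep(1, 5)), "waveform")
  expect_error(synth_case_config(waveform = rep(-1, 32)), "waveform")
  expect_error(make_cohort(n_cases = 1), "at least 2")
})

test_that("cohorts produce paired tables; tiny cohorts are flagged underpowered", {
  coh <- make_cohort(n_cases = 2, seed = 5, with_images = FALSE)
  s <- coh$samples
  expect_identical(sort(unique(s$case_id)), c(1L, 2L))
  expect_setequal(unique(s$hp_kind),
                  c("pressure", "wss", "osi", "wss_norm", "osi_norm", "chp"))
  expect_true(all(is.finite(s$more)) && all(is.finite(s$less)))
  rep2 <- run_cohort(coh)
  expect_true(all(rep2$hp_table$test_used == "underpowered"))
  expect_true(all(is.na(rep2$hp_table$p_value)))
  expect_true(is.na(rep2$correspondence$fraction))
})

test_that("WSS is significant and pressure is not in at least 90% of cohort seeds", {
  # 100 Monte-Carlo cohorts; a coarser mesh keeps the quadrature identical
  # in form while shrinking the per-case cost
  base <- synth_case_config(n_theta = 16, n_phi = 32)
  hits_wss <- hits_prs <- logical(100)
  for (s in 1:100) {
    coh <- make_cohort(21, base_config = base, seed = s, with_images = FALSE)
    g <- function(k) coh$samples[coh$samples$hp_kind == k, ]
    hits_wss[s] <- compare_groups(g("wss")$more, g("wss")$less)$p_value < 0.05
    hits_prs[s] <- compare_groups(g("pressure")$more,
                                  g("pressure")$less)$p_value >= 0.05
  }
  expect_gte(mean(hits_wss), 0.9)
  expect_gte(mean(hits_prs), 0.9)
})

test_that("cohort effect defaults plant the clinical contrast pattern", {
  coh <- make_cohort(n_cases = 21, seed = 8, with_images = FALSE)
  s <- coh$samples
  g <- function(k) s[s$hp_kind == k, ]
  p_wss <- compare_groups(g("wss")$more, g("wss")$less)$p_value
  p_osi <- compare_groups(g("osi")$more, g("osi")$less)$p_value
  p_prs <- compare_groups(g("pressure")$more, g("pressure")$less)$p_value
  expect_lt(p_wss, 0.05)         # strong low-WSS effect at the thin wall
  expect_lt(p_wss, p_osi)        # WSS more predictive than OSI
  expect_gt(p_prs, 0.3)          # pressure carries no signal
  expect_lt(mean(g("wss")$more), mean(g("wss")$less))
  expect_gt(mean(g("osi")$more), mean(g("osi")$less))
})
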