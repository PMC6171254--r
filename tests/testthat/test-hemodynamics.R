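test_that("wss_from_gradient is the viscosity-shear product with guarded domain", {
  expect_identical(wss_from_gradient(0.004, 0), 0)
  expect_equal(wss_from_gradient(0.004, 250), 1.0)
  expect_identical(wss_from_gradient(1.0, 1.0), 1.0)
  expect_equal(wss_from_gradient(0.004, c(0, 250, 500)), c(0, 1, 2))
  expect_error(wss_from_gradient(-0.004, 10), "viscosity")
  expect_error(wss_from_gradient(0.004, -1), "shear_rate")
})

test_that("wss_magnitude_at returns per-face Euclidean norms", {
  s <- uniform_series(rbind(c(3, 4, 0), c(0, 0, 0), c(1, 1, 1)))
  expect_equal(as.numeric(wss_magnitude_at(s, 1)), c(5, 5))
  expect_equal(as.numeric(wss_magnitude_at(s, 2)), c(0, 0))
  expect_equal(as.numeric(wss_magnitude_at(s, 3)), rep(sqrt(3), 2))
  expect_identical(attr(wss_magnitude_at(s, 1), "kind"), "wss_magnitude")
  expect_error(wss_magnitude_at(s, 0), "out of range")
  expect_error(wss_magnitude_at(s, 4), "out of range")
})

test_that("OSI is 0 for constant direction, 0.5 for symmetric full reversal", {
  # constant direction, time-varying magnitude
  mags <- c(0.5, 2, 1, 3, 0.25, 1.5, 2.5, 0.75)
  s <- uniform_series(cbind(mags, 0, 0))
  expect_equal(as.numeric(compute_osi(s)), c(0, 0), tolerance = 1e-12)

  # two equal half-cycles with opposite direction: exact 0.5
  vecs <- rbind(matrix(rep(c(1.3, 0.4, 0), 16), 16, 3, byrow = TRUE),
                matrix(rep(-c(1.3, 0.4, 0), 16), 16, 3, byrow = TRUE))
  expect_identical(as.numeric(compute_osi(uniform_series(vecs))), c(0.5, 0.5))
})

test_that("OSI matches an independent cyclic trapezoid oracle", {
  # 3-sample series along one axis, non-uniform times
  times <- c(0, 0.3, 0.7); period <- 1
  vals <- c(2, -1, 0.5)
  s <- uniform_series(cbind(vals, 0, 0), times = times, period = period)
  num <- abs(trapz_cyclic_oracle(times, vals, period))
  den <- trapz_cyclic_oracle(times, abs(vals), period)
  expect_equal(as.numeric(compute_osi(s))[1], 0.5 * (1 - num / den),
               tolerance = 1e-15)

  # engineered integrals: |int wss dt| = 0.6, int |wss| dt = 1.0 -> OSI 0.2
  vals <- c(3.2, -0.8, 0, 0)  # uniform dt = 0.25: sums 2.4 and 4.0
  s <- uniform_series(cbind(vals, 0, 0))
  expect_equal(as.numeric(compute_osi(s))[1], 0.2, tolerance = 1e-12)
})

test_that("OSI is invariant to uniform positive rescaling and zero flow gives 0", {
  for (seed in 1:5) {
    set.seed(seed)
    vecs <- matrix(rnorm(12 * 3), 12, 3)
    s1 <- uniform_series(vecs)
    s2 <- uniform_series(vecs * 37.5)
    o1 <- as.numeric(compute_osi(s1)); o2 <- as.numeric(compute_osi(s2))
    expect_equal(o1, o2, tolerance = 1e-12)
    expect_true(all(o1 >= 0 & o1 <= 0.5))
  }
  s0 <- uniform_series(matrix(0, 8, 3))
  expect_equal(as.numeric(compute_osi(s0)), c(0, 0))
})

test_that("sac_extremes restrict to the mask and reject degenerate ranges", {
  mesh <- dome <- flat_quad_mesh()
  f3 <- scalar_field(c(0.2, 3.0), "wss_magnitude")
  ext <- sac_extremes(f3, all_sac(mesh))
  expect_equal(ext$wss_min, 0.2)
  expect_equal(ext$wss_max, 3.0)
  # non-sac faces carry larger values but are ignored
  m1 <- sac_mask(c(TRUE, FALSE), mesh)
  f <- scalar_field(c(1.0, 50), "wss_magnitude")
  expect_error(sac_extremes(f, m1), "degenerate")
  f2 <- scalar_field(c(1.0, 1.0), "wss_magnitude")
  expect_error(sac_extremes(f2, all_sac(mesh)), "degenerate")
})

test_that("WSS normalization solves the quartic ellipse relation on [0, 1]", {
  mesh <- flat_quad_mesh()
  ext <- sac_extremes(scalar_field(c(0.1, 2.0), "wss_magnitude"),
                      all_sac(mesh))
  wn <- wss_norm(scalar_field(c(0.1, 2.0), "wss_magnitude"), ext)
  expect_identical(as.numeric(wn), c(1, 0))
  mid <- (0.1 + 2.0) / 2
  wn_mid <- wss_norm(scalar_field(rep(mid, 2), "wss_magnitude"), ext)
  expect_equal(as.numeric(wn_mid)[1], 1 - (15 / 16)^(1 / 4),
               tolerance = 1e-12)
  # residual of the quartic on a dense grid, and monotonicity
  grid <- seq(0.1, 2.0, length.out = 2001)
  x <- as.numeric(wss_norm(scalar_field(grid, "wss_magnitude"), ext))
  u <- (grid - 2.0) / (2.0 - 0.1)
  expect_lt(max(abs((x - 1)^4 + u^4 - 1)), 1e-9)
  expect_true(all(diff(x) <= 1e-12))
  # clamping outside the sac range keeps the field in [0, 1]
  out <- wss_norm(scalar_field(c(0.01, 7), "wss_magnitude"), ext)
  expect_identical(as.numeric(out), c(1, 0))
})

test_that("OSI normalization doubles the index onto [0, 1]", {
  f <- scalar_field(c(0, 0.5, 0.073), "osi")
  expect_equal(as.numeric(osi_norm(f)), c(0, 1, 0.146))
  expect_error(scalar_field(c(0.6), "osi"), "outside")
})

test_that("CHP is the weighted average, linear in w1", {
  wssn <- scalar_field(c(0.8, 0.3), "wss_norm")
  osin <- scalar_field(c(0.2, 0.7), "osi_norm")
  expect_equal(as.numeric(chp(wssn, osin, weighting(0.5)))[1], 0.5)
  expect_identical(as.numeric(chp(wssn, osin, weighting(1))),
                   as.numeric(wssn))
  expect_identical(as.numeric(chp(wssn, osin, weighting(0))),
                   as.numeric(osin))
  # mean CHP affine in w1
  for (w1 in seq(0, 1, 0.25)) {
    got <- mean(chp(wssn, osin, weighting(w1)))
    expect_equal(got, w1 * mean(wssn) + (1 - w1) * mean(osin),
                 tolerance = 1e-12)
  }
  expect_error(chp(wssn, scalar_field(0.1, "osi_norm"), weighting(1)),
               "face counts")
  expect_error(weighting(0.6, 0.5), "sum to 1")
  expect_error(weighting(-0.1, 1.1), "non-negative")
})

test_that("peak_region honors radius, area weighting and tie-breaks", {
  mesh <- flat_quad_mesh()
  mask <- all_sac(mesh)
  f <- scalar_field(c(0.2, 0.9), "chp")
  pk0 <- peak_region(f, mask, mesh, patch_radius = 0, mode = "max")
  expect_identical(pk0$seed_face, 2L)
  expect_identical(pk0$patch_faces, 2L)
  expect_equal(pk0$patch_mean, 0.9)
  pk_min <- peak_region(f, mask, mesh, patch_radius = 0, mode = "min")
  expect_identical(pk_min$seed_face, 1L)
  # uniform field: tie broken to the lowest-index sac face
  fu <- scalar_field(c(0.4, 0.4), "chp")
  expect_identical(peak_region(fu, mask, mesh, 0.5)$seed_face, 1L)
  expect_identical(
    peak_region(fu, sac_mask(c(FALSE, TRUE), mesh), mesh, 0.5)$seed_face, 2L)
  # patch mean is the area-weighted mean over patch faces
  pk <- peak_region(f, mask, mesh, patch_radius = 10)
  a <- mesh$face_areas
  expect_equal(pk$patch_mean, sum(as.numeric(f) * a) / sum(a),
               tolerance = 1e-12)
  expect_true(pk$seed_face %in% pk$patch_faces)
  expect_error(peak_region(f, mask, mesh, patch_radius = -1), ">= 0")
})

test_that("the planted low-shear patch is recovered as the peak-CHP region", {
  case <- make_case(synth_case_config(seed = 11))
  hf <- hemodynamic_fields(case$series, case$sac)
  pk <- peak_region(hf$chp, case$sac, case$series$mesh, 0.5)
  expect_true(case$ground_truth$twa_face_mask[pk$seed_face])
  # diastolic estimate lands on the waveform minimum (first sample)
  expect_identical(diastolic_index_estimate(case$series, case$sac), 1L)
})
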