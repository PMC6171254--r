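test_that("sRGB to CIELAB conversion has the standard axis semantics", {
  lab <- srgb_to_lab(rbind(c(255, 255, 255), c(0, 0, 0),
                           c(255, 0, 0), c(0, 255, 0)))
  expect_equal(lab[1, 1], 100, tolerance = 1e-3)
  expect_lt(max(abs(lab[1, 2:3])), 0.05)      # white: neutral
  expect_equal(lab[2, ], c(0, 0, 0), ignore_attr = TRUE, tolerance = 1e-6)
  expect_gt(lab[3, 2], 0)                      # red: a* > 0
  expect_lt(lab[4, 2], 0)                      # green: a* < 0
  # gray ramp stays neutral
  g <- seq(0, 255, by = 5)
  ramp <- srgb_to_lab(cbind(g, g, g))
  expect_lt(max(abs(ramp[, 2])), 0.5)
  expect_lt(max(abs(ramp[, 3])), 0.5)
  expect_true(all(diff(ramp[, 1]) > 0))
  expect_error(srgb_to_lab(rbind(c(-1, 0, 0))), "0..255")
})

test_that("ciede2000 reproduces the published verification pairs to 1e-4", {
  ref <- ciede2000_reference_pairs()
  got <- ciede2000(ref$lab_a, ref$lab_b)
  expect_equal(got, ref$de, tolerance = 1e-4)
  expect_lt(max(abs(got - ref$de)), 1e-4)
})

test_that("ciede2000 is symmetric and zero only for identical colors", {
  set.seed(42)
  for (i in 1:20) {
    a <- c(runif(1, 0, 100), runif(2, -60, 60))
    b <- c(runif(1, 0, 100), runif(2, -60, 60))
    expect_equal(ciede2000(a, b), ciede2000(b, a), tolerance = 1e-12)
    expect_gte(ciede2000(a, b), 0)
    expect_identical(ciede2000(a, a), 0)
  }
  expect_error(ciede2000(c(50, NA, 0), c(50, 0, 0)), "finite")
})

test_that("reference_color averages the annotated circle", {
  lab <- array(0, c(10, 10, 3))
  lab[, , 1] <- 40; lab[, , 2] <- 25; lab[, , 3] <- 10
  ann <- region_annotation(4, 4, 2.5, "reference")
  rc <- reference_color(lab, ann)
  expect_equal(c(rc$L2, rc$a2, rc$b2), c(40, 25, 10))
  # half L = 40, half L = 60 -> mean 50 (split along columns)
  lab2 <- lab; lab2[, 6:10, 1] <- 60
  rc2 <- reference_color(lab2, region_annotation(4.5, 4.5, 20, "reference"))
  expect_equal(rc2$L2, 50)
  expect_error(
    reference_color(lab, region_annotation(100, 100, 2, "reference")),
    "no image pixels")
  expect_error(reference_color(lab, region_annotation(4, 4, 2, "roi")),
               "reference")
})

test_that("delta_e_map is zero at the reference color and non-negative", {
  lab <- array(0, c(6, 8, 3))
  lab[, , 1] <- 50; lab[, , 2] <- 20; lab[, , 3] <- 15
  lab[3, 5, ] <- c(60, 35, 15)
  rc <- reference_color(lab, region_annotation(1, 1, 1.2, "reference"))
  dm <- delta_e_map(lab, rc)
  expect_identical(dim(dm), c(6L, 8L))
  expect_true(all(unclass(dm) >= 0))
  expect_equal(dm[1, 1], 0, tolerance = 1e-12)
  expect_gt(dm[3, 5], 1)
  # constant image -> constant map
  lab0 <- lab; lab0[3, 5, ] <- c(50, 20, 15)
  expect_equal(max(unclass(delta_e_map(lab0, rc))), 0, tolerance = 1e-9)
})

test_that("the redness projection scales the raw map by a constant in [0, 1]", {
  lab <- array(0, c(12, 12, 3))
  set.seed(7)
  lab[, , 1] <- 50 + rnorm(144, 0, 8)
  lab[, , 2] <- 22 + rnorm(144, 0, 6)
  lab[, , 3] <- 18 + rnorm(144, 0, 6)
  rc <- reference_color(lab, region_annotation(5, 5, 3, "reference"))
  raw <- delta_e_map(lab, rc)
  mod <- modify_delta_e(raw, rc)
  expect_true(all(unclass(mod) <= unclass(raw) + 1e-12))
  ratio <- unclass(mod)[unclass(raw) > 0] / unclass(raw)[unclass(raw) > 0]
  expect_lt(diff(range(ratio)), 1e-12)         # one constant per image
  c0 <- ratio[1]
  expect_true(c0 >= 0 && c0 <= 1)
  expect_equal(c0, rc$a2^2 / (rc$L2^2 + rc$a2^2), tolerance = 1e-12)
  # ranking of pixels is unchanged
  expect_identical(order(unclass(raw)), order(unclass(mod)))
})

test_that("modify_delta_e evaluates the printed factor and its variants", {
  mk_ref <- function(L, a) structure(list(L2 = L, a2 = a, b2 = 0,
                                          n_pixels = 1),
                                     class = "reference_color")
  raw <- structure(matrix(10, 2, 2), modified = FALSE, class = "delta_e_map")
  expect_equal(unclass(modify_delta_e(raw, mk_ref(40, 30)))[1, 1],
               10 * 900 / 2500)                     # 3.6
  expect_equal(max(unclass(modify_delta_e(raw, mk_ref(50, 0)))), 0)
  expect_equal(unclass(modify_delta_e(raw, mk_ref(0, 30)))[1, 1], 10)
  expect_equal(unclass(modify_delta_e(raw, mk_ref(40, 30),
                                      variant = "projection"))[1, 1],
               10 * 30 / 50)
  expect_error(modify_delta_e(raw, mk_ref(0, 0)), "undefined")
  expect_error(modify_delta_e(modify_delta_e(raw, mk_ref(40, 30)),
                              mk_ref(40, 30)), "raw")
})

test_that("reddest_region finds a planted blob and breaks ties row-major", {
  m <- matrix(1, 20, 30)
  m[8:12, 18:22] <- 5                  # bright blob
  map <- structure(m, modified = TRUE, class = "delta_e_map")
  pk <- reddest_region(map, patch_radius = 2)
  expect_true(pk$y + 1 >= 8 && pk$y + 1 <= 12)
  expect_true(pk$x + 1 >= 18 && pk$x + 1 <= 22)
  # uniform map: first ROI pixel by smallest row then column
  u <- structure(matrix(2, 10, 10), modified = TRUE, class = "delta_e_map")
  pk_u <- reddest_region(u, patch_radius = 0)
  expect_identical(c(pk_u$x, pk_u$y), c(0L, 0L))
  roi <- region_annotation(6, 5, 2, "roi")
  pk_roi <- reddest_region(u, roi = roi, patch_radius = 0)
  expect_identical(pk_roi$y, 3L)       # top row of the circle
  # radius 0 is the raw argmax
  m2 <- matrix(0, 5, 5); m2[4, 2] <- 9
  map2 <- structure(m2, modified = TRUE, class = "delta_e_map")
  pk2 <- reddest_region(map2, patch_radius = 0)
  expect_identical(c(pk2$x, pk2$y), c(1L, 3L))
  expect_error(reddest_region(map2, region_annotation(500, 500, 3, "roi")),
               "no image pixels")
})

test_that("the reddish patch of the synthetic dome is recovered for every seed", {
  for (seed in c(3, 14, 27)) {
    case <- make_case(synth_case_config(seed = seed))
    ia <- analyze_image(case$image, case$ground_truth$annotations)
    expect_true(case$ground_truth$twa_pixel_mask[ia$peak$y + 1, ia$peak$x + 1],
                label = paste("seed", seed))
  }
})

test_that("more dangerous regions score higher modified color differences", {
  case <- make_case(synth_case_config(seed = 5))
  ia <- analyze_image(case$image, case$ground_truth$annotations)
  expect_gt(ia$annotation_means[["more_dangerous"]],
            ia$annotation_means[["less_dangerous"]])
})
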