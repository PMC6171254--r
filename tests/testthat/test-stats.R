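test_that("the normality gate routes normal data to the t-test", {
  set.seed(1)
  a <- rnorm(50); b <- rnorm(50, 1)
  expect_identical(normality_gate(a, b), "t_test")
  # heavily discretized two-point data is rejected as non-normal
  x <- rep(c(0, 1), each = 12)
  expect_identical(normality_gate(x, rnorm(20)), "mann_whitney_u")
  expect_identical(normality_gate(rnorm(20), x), "mann_whitney_u")
  # alpha = 0: nothing can fail the gate
  expect_identical(normality_gate(x, x + 0.5, alpha = 0), "t_test")
  expect_error(normality_gate(c(1, 2), rnorm(10)), "n >= 3")
})

test_that("compare_groups reports means, SDs and a gated two-sided test", {
  set.seed(202)
  x <- rnorm(21, 5, 1)
  same <- compare_groups(x, x)
  expect_identical(same$test_used, "t_test")
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  expect_equal(same$statistic, 0, tolerance = 1e-9)
  expect_equal(same$mean_more, mean(x))
  expect_equal(same$sd_more, sd(x))       # n-1 denominator

  shifted <- compare_groups(x + 10 * sd(x), x)
  expect_lt(shifted$p_value, 1e-6)

  expect_error(compare_groups(rep(2, 5), rep(2, 5)), "degenerate")
  expect_error(compare_groups(c(1, 2), c(3, 4, 5)), "3 cases")
})

test_that("compare_groups is invariant to case ordering", {
  set.seed(303)
  x <- rexp(15); y <- rexp(15, 0.5)
  r1 <- compare_groups(x, y)
  r2 <- compare_groups(sample(x), sample(y))
  expect_identical(r1$test_used, r2$test_used)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
})

test_that("Mann-Whitney U matches exhaustive rank enumeration for n <= 8", {
  fixtures <- list(
    list(x = c(1.2, 3.4, 0.5, 2.2), y = c(4.5, 6.1, 2.9)),
    list(x = c(10, 12, 14, 16, 18), y = c(11, 13, 15, 17)),
    list(x = c(0.1, 0.2, 0.3), y = c(5, 6, 7, 8)),
    list(x = c(1, 1, 2, 3), y = c(2, 2, 4)),           # ties
    list(x = c(5, 5, 5, 1), y = c(5, 5, 2, 2))         # heavy ties
  )
  for (f in fixtures) {
    got <- twachp:::mann_whitney_u(f$x, f$y)
    want <- mwu_brute_force(f$x, f$y)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-9,
                 label = paste("p for", paste(f$x, collapse = ",")))
  }
  # tie-free case also agrees with the closed-form exact distribution
  x <- c(1.2, 3.4, 0.5, 2.2); y <- c(4.5, 6.1, 2.9)
  ref <- wilcox.test(x, y, exact = TRUE)
  got <- twachp:::mann_whitney_u(x, y)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("weight_sweep means are affine in w1 and degenerate to raw fields", {
  set.seed(404)
  n <- 21
  wm <- runif(n, 0.3, 0.9); om <- runif(n, 0.05, 0.4)
  wl <- runif(n, 0.0, 0.2); ol <- runif(n, 0.0, 0.3)
  sw <- weight_sweep(wm, om, wl, ol, w1_grid = seq(0, 1, 0.1))
  expect_identical(nrow(sw), 11L)
  expect_true(all(diff(sw$w1) > 0))
  # affine: mean(w1) = w1 * mean(wssn) + (1 - w1) * mean(osin)
  expect_equal(sw$mean_more, sw$w1 * mean(wm) + sw$w2 * mean(om),
               tolerance = 1e-12)
  expect_equal(sw$mean_less, sw$w1 * mean(wl) + sw$w2 * mean(ol),
               tolerance = 1e-12)
  # w1 = 1 row equals the comparison of the raw normalized WSS values
  raw <- compare_groups(wm, wl, hp_kind = "chp")
  last <- sw[sw$w1 == 1, ]
  expect_equal(last$p_value, raw$p_value, tolerance = 1e-12)
  expect_equal(last$mean_more, raw$mean_more)
  expect_error(weight_sweep(wm, om, wl, ol, w1_grid = c(0.5, 1.2)),
               "\\[0, 1\\]")
  expect_error(weight_sweep(wm, om[-1], wl, ol), "equal length")
})
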