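#' Normality-gated choice of two-group test
#'
#' The comparison protocol tests each group for normality with the
#' Shapiro-Wilk test; only if both groups look normal (p >= `alpha`) is the
#' t-test used, otherwise the Mann-Whitney U test. A sample on which
#' Shapiro-Wilk is undefined (all values identical) is treated as
#' non-normal.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 3.
#' @param alpha significance level of the gate (default 0.05, the same
#'   threshold used for the comparison itself).
#' @return `"t_test"` or `"mann_whitney_u"`.
#' @export
normality_gate <- function(sample_a, sample_b, alpha = 0.05) {
  for (s in list(sample_a, sample_b)) {
    if (length(s) < 3L) stop("normality gate needs n >= 3 per group")
    if (any(!is.finite(s))) stop("samples must be finite")
  }
  p_of <- function(s) {
    if (stats::sd(s) == 0) return(0)       # degenerate: not normal
    stats::shapiro.test(s)$p.value
  }
  if (p_of(sample_a) >= alpha && p_of(sample_b) >= alpha) "t_test"
  else "mann_whitney_u"
}

# Exact two-sided Mann-Whitney U by permutation enumeration over group
# assignments (handles ties); used for small samples where the closed-form
# exact distribution is unavailable.
mwu_exact_enumeration <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2L, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  list(statistic = u_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}

# Mann-Whitney U, two-sided: exact for small samples (enumeration when ties
# defeat the closed-form exact distribution), normal approximation with tie
# correction otherwise.
mann_whitney_u <- function(x, y, exact_max_n = 8L) {
  small <- length(x) <= exact_max_n && length(y) <= exact_max_n
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (small && has_ties) {
    res <- mwu_exact_enumeration(x, y)
    return(list(statistic = res$statistic, p_value = res$p_value,
                method = "exact enumeration"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = small,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (small) "exact" else "normal approximation")
}

#' Two-group comparison of a hemodynamic parameter
#'
#' Compares the values of one hemodynamic parameter between the more
#' dangerous (max redness) and less dangerous regions across cases: group
#' means and sample SDs (n-1 denominator), the normality-gated test
#' ([normality_gate()]), and its two-sided p-value. Groups are treated as
#' independent by default; `paired = TRUE` switches to the paired t-test /
#' Wilcoxon signed-rank test.
#'
#' @param more,less numeric vectors of per-case values at the two regions.
#' @param alpha gate significance level.
#' @param paired compare as paired samples.
#' @param hp_kind optional label carried into the result.
#' @return An object of class `group_comparison`: list with `hp_kind`,
#'   `n_more`, `n_less`, `mean_more`, `sd_more`, `mean_less`, `sd_less`,
#'   `test_used`, `statistic`, `p_value`.
#' @export
compare_groups <- function(more, less, alpha = 0.05, paired = FALSE,
                           hp_kind = NA_character_) {
  more <- as.numeric(more); less <- as.numeric(less)
  if (any(!is.finite(more)) || any(!is.finite(less)))
    stop("group values must be finite")
  if (length(more) < 3L || length(less) < 3L)
    stop("compare_groups needs at least 3 cases per group")
  if (paired && length(more) != length(less))
    stop("paired comparison needs equal group lengths")
  pooled <- c(more, less)
  if (max(pooled) - min(pooled) == 0)
    stop("all values identical in both groups: comparison degenerate")

  test_used <- normality_gate(more, less, alpha)
  if (test_used == "t_test") {
    tt <- stats::t.test(more, less, alternative = "two.sided",
                        var.equal = FALSE, paired = paired)
    statistic <- unname(tt$statistic); p <- tt$p.value
  } else if (paired) {
    wt <- suppressWarnings(
      stats::wilcox.test(more, less, paired = TRUE,
                         alternative = "two.sided"))
    statistic <- unname(wt$statistic); p <- wt$p.value
  } else {
    mw <- mann_whitney_u(more, less)
    statistic <- mw$statistic; p <- mw$p_value
  }
  structure(
    list(hp_kind = hp_kind,
         n_more = length(more), n_less = length(less),
         mean_more = mean(more), sd_more = stats::sd(more),
         mean_less = mean(less), sd_less = stats::sd(less),
         test_used = test_used, statistic = statistic,
         p_value = p, alpha = alpha, paired = paired),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: more %.4g +/- %.4g, less %.4g +/- %.4g  [%s%s, p = %.3g]\n",
    if (is.na(x$hp_kind)) "comparison" else x$hp_kind,
    x$mean_more, x$sd_more, x$mean_less, x$sd_less,
    x$test_used, if (x$paired) ", paired" else "", x$p_value))
  invisible(x)
}

#' Weighting-factor sweep of the combined hemodynamic parameter
#'
#' For each weight `w1` in the grid, per-case CHP values are formed at both
#' regions from the supplied normalized WSS and normalized OSI values
#' (`chp = w1 * wss_norm + (1 - w1) * osi_norm`) and the two groups compared
#' with [compare_groups()]. The group mean CHP is exactly linear in `w1`.
#'
#' @param wssn_more,osin_more per-case normalized WSS / OSI at the more
#'   dangerous region.
#' @param wssn_less,osin_less the same at the less dangerous region.
#' @param w1_grid weights for the normalized WSS, each in \[0, 1\].
#' @param alpha gate significance level.
#' @param paired passed to [compare_groups()].
#' @return A data.frame of class `weight_sweep` with one row per `w1`
#'   (ordered increasing): `w1`, `w2`, `mean_more`, `sd_more`, `mean_less`,
#'   `sd_less`, `test_used`, `statistic`, `p_value`.
#' @export
weight_sweep <- function(wssn_more, osin_more, wssn_less, osin_less,
                         w1_grid = seq(0.5, 1, by = 0.1), alpha = 0.05,
                         paired = FALSE) {
  n <- length(wssn_more)
  if (length(osin_more) != n || length(wssn_less) != n ||
      length(osin_less) != n)
    stop("per-case value vectors must have equal length")
  if (any(!is.finite(w1_grid)) || any(w1_grid < 0) || any(w1_grid > 1))
    stop("`w1_grid` must lie in [0, 1]")
  w1_grid <- sort(w1_grid)
  rows <- lapply(w1_grid, function(w1) {
    cmp <- compare_groups(w1 * wssn_more + (1 - w1) * osin_more,
                          w1 * wssn_less + (1 - w1) * osin_less,
                          alpha = alpha, paired = paired, hp_kind = "chp")
    data.frame(w1 = w1, w2 = 1 - w1,
               mean_more = cmp$mean_more, sd_more = cmp$sd_more,
               mean_less = cmp$mean_less, sd_less = cmp$sd_less,
               test_used = cmp$test_used, statistic = cmp$statistic,
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("weight_sweep", "data.frame")
  out
}
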