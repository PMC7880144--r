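#' One-way ANOVA with eta-squared effect size
#'
#' Classical between/within decomposition across k groups, with effect
#' size reported as eta-squared = SS_between / SS_total — the proportion
#' of total variance carried by the group factor. With two groups the F
#' statistic equals the square of the pooled two-sample t statistic. When
#' every group is internally constant but the groups differ, the
#' within-group sum of squares is zero: the statistic is reported as
#' `Inf` with `degenerate = TRUE` and effect size 1.
#'
#' @param groups Named list of numeric vectors, one per condition, each of
#'   length >= 2.
#' @return A list of class `load_test` with `method`, `statistic`, `df`
#'   (length 2), `p_value`, `effect_size`, `degenerate`.
#' @export
oneway_anova <- function(groups) {
  check_groups(groups, min_groups = 2L)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  ssb <- tab[1, "Sum Sq"]; ssw <- tab[2, "Sum Sq"]
  df1 <- tab[1, "Df"]; df2 <- tab[2, "Df"]
  degenerate <- ssw <= .Machine$double.eps * max(1, ssb)
  if (degenerate) {
    stat <- Inf; p <- 0; eta <- if (ssb > 0) 1 else 0
    if (ssb == 0) { stat <- 0; p <- 1 }
  } else {
    stat <- tab[1, "F value"]; p <- tab[1, "Pr(>F)"]
    eta <- ssb / (ssb + ssw)
  }
  new_load_test("one-way ANOVA", stat, c(df1, df2), p, effect_size = eta,
                degenerate = degenerate)
}

check_groups <- function(groups, min_groups = 2L) {
  if (!is.list(groups) || length(groups) < min_groups)
    stopf("need at least %d groups", min_groups)
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stopf("insufficient data: every group needs >= 2 values")
  invisible(groups)
}

new_load_test <- function(method, statistic, df, p_value,
                          effect_size = NA_real_, degenerate = FALSE) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, effect_size = effect_size,
                 degenerate = degenerate),
            class = "load_test")
}

#' @export
print.load_test <- function(x, ...) {
  dfs <- paste(signif(x$df, 6), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g", x$method,
              x$statistic, dfs, x$p_value))
  if (is.finite(x$effect_size)) cat(sprintf(", eta^2 = %.3f", x$effect_size))
  if (isTRUE(x$degenerate)) cat("  [degenerate: zero within-group variance]")
  cat("\n")
  invisible(x)
}

#' Pairwise two-sample t-tests between all condition pairs
#'
#' One test per unordered pair of groups. Pooled-variance Student tests by
#' default; `paired = TRUE` for within-participant designs (requires equal
#' group sizes). No multiple-comparison correction is applied by default;
#' pass e.g. `p_adjust = "holm"` to correct.
#'
#' @param groups Named list of numeric vectors (each length >= 2).
#' @param paired Paired tests?
#' @param var_equal Pooled-variance tests (default `TRUE`); `FALSE` gives
#'   Welch tests.
#' @param p_adjust Correction method for [stats::p.adjust()]
#'   (default `"none"`).
#' @return data.frame with one row per pair: `group1`, `group2`,
#'   `statistic`, `df`, `p_value`, `p_adjusted`.
#' @export
pairwise_ttests <- function(groups, paired = FALSE, var_equal = TRUE,
                            p_adjust = "none") {
  check_groups(groups, min_groups = 2L)
  labs <- names(groups) %||% as.character(seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  rows <- apply(pairs, 2, function(ij) {
    a <- groups[[ij[1]]]; b <- groups[[ij[2]]]
    ht <- stats::t.test(a, b, paired = paired, var.equal = var_equal)
    data.frame(group1 = labs[ij[1]], group2 = labs[ij[2]],
               statistic = unname(ht$statistic), df = unname(ht$parameter),
               p_value = ht$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Unequal-variance (Welch) t-test
#'
#' Two-sample t-test with the Welch-Satterthwaite degrees of freedom,
#' appropriate when the two samples have different variances — e.g.
#' comparing 5-second fixation counts between a maneuvering and a
#' non-maneuvering flight.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A `load_test` (no effect size).
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stopf("insufficient data: both samples need >= 2 values")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  new_load_test("Welch two-sample t-test", unname(ht$statistic),
                unname(ht$parameter), ht$p.value)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length >= 3; each must have nonzero
#'   variance.
#' @return A list of class `load_cor` with `r`, `p_value`, `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("undefined correlation: zero-variance input")
  ht <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ht$estimate), p_value = ht$p.value,
                 n = length(x)),
            class = "load_cor")
}

#' @export
print.load_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.3f, p = %.4g (n = %d)\n",
              x$r, x$p_value, x$n))
  invisible(x)
}

#' Resample two differently-timed series onto a common grid
#'
#' Linear interpolation of both series onto an even grid covering the
#' overlap of their time ranges, so that quantities sampled on different
#' clocks (e.g. a fixation-rate series and a vertical-speed series) can be
#' correlated point by point.
#'
#' @param t1,x1 First series.
#' @param t2,x2 Second series.
#' @param n Number of grid points (default 100).
#' @return data.frame `t, x1, x2`.
#' @export
align_series <- function(t1, x1, t2, x2, n = 100L) {
  lo <- max(min(t1), min(t2)); hi <- min(max(t1), max(t2))
  if (hi <= lo) stopf("series do not overlap in time")
  grid <- seq(lo, hi, length.out = n)
  data.frame(t = grid,
             x1 = stats::approx(t1, x1, xout = grid)$y,
             x2 = stats::approx(t2, x2, xout = grid)$y)
}

#' Signed vertical speed from an altitude series
#'
#' Central-difference time derivative of altitude: negative while the
#' aircraft descends, positive in a climb (onboard recorders often log
#' only the magnitude of vertical velocity; the sign is recovered from the
#' altitude trace).
#'
#' @param t Timestamps, seconds.
#' @param altitude Altitude, ft.
#' @param half_window Differencing half-window, samples.
#' @return Signed vertical speed, ft/s, `NA` at the edges.
#' @export
rate_of_descent <- function(t, altitude, half_window = 1L) {
  if (length(t) < 2L) stopf("need >= 2 samples")
  central_diff(altitude, t, half_window)
}
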