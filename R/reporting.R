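#' Bland-Altman agreement analysis
#'
#' Pairwise means and differences of two measurement series, the mean
#' difference (bias), the standard deviation of the differences, the limits
#' of agreement (mean difference +/- 1.96 SD), and the fraction of pairs
#' falling within those limits.
#'
#' @param x,y equal-length numeric vectors (two methods measuring the same
#'   quantity).
#' @return list of class `bland_altman` with `means`, `differences`,
#'   `mean_diff`, `sd_diff`, `lower`, `upper`, `within_limits` (count) and
#'   `within_fraction`; degenerate (zero-SD) limits are flagged.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need at least two pairs")
  d <- y - x
  m <- (x + y) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  lower <- md - 1.96 * sdd
  upper <- md + 1.96 * sdd
  within <- sum(d >= lower & d <= upper)
  structure(list(
    means = m, differences = d, mean_diff = md, sd_diff = sdd,
    lower = lower, upper = upper, within_limits = within,
    within_fraction = within / length(d), degenerate = sdd == 0
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: mean diff %.4g, SD %.4g, limits [%.4g, %.4g], %d/%d (%.1f%%) within\n",
    x$mean_diff, x$sd_diff, x$lower, x$upper, x$within_limits,
    length(x$differences), 100 * x$within_fraction
  ))
  if (x$degenerate) cat("  (degenerate limits: zero SD of differences)\n")
  invisible(x)
}

#' Coefficient of determination
#'
#' Squared Pearson correlation of two paired series.
#'
#' @param x,y equal-length numeric vectors; `x` must not be constant.
#' @return R^2 in [0, 1].
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need at least two pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  stats::cor(x, y)^2
}

#' Quartile summary
#'
#' MIN, Q1 (lower quartile), Q2 (median), Q3 (upper quartile), MAX and AVG
#' of a sample; quartiles use linear interpolation between order statistics.
#'
#' @param values nonempty numeric vector.
#' @return named list (MIN, Q1, Q2, Q3, MAX, AVG).
#' @export
quartile_summary <- function(values) {
  if (length(values) < 1) stop("empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(MIN = min(values), Q1 = q[1], Q2 = q[2], Q3 = q[3],
       MAX = max(values), AVG = mean(values))
}
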