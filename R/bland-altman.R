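#' Bland-Altman agreement statistics for a two-session table
#'
#' For per-subject differences `d = session1 - session2` (positive values
#' indicate larger measures in session one):
#' * **bias** = mean(d), with a t-based 95% CI
#'   `bias +/- t(n-1, 0.975) * sd(d) / sqrt(n)`;
#' * **limits of agreement** = `bias +/- 1.96 * sd(d)`, the range expected to
#'   cover ~95% of individual between-session differences, with the classical
#'   standard-error approximation `sd(d) * sqrt(3/n)`;
#' * **slope** = OLS slope of `d` on the per-subject session means
#'   `(session1 + session2) / 2`, with its two-sided p-value (proportional
#'   bias; no multiplicity adjustment).
#'
#' @param x numeric matrix with columns session 1 and session 2 (n >= 3).
#' @param conf confidence level for the bias CI (default 0.95).
#' @param loa_mult multiplier for the limits of agreement (default 1.96).
#' @return an object of class `ba_result`: list with `bias`, `bias_ci_low`,
#'   `bias_ci_high`, `sd_diff`, `loa_low`, `loa_high`, `loa_se`, `slope`,
#'   `slope_p`, `n`.
#' @examples
#' x <- cbind(c(10, 12, 14, 16), c(9, 12, 13, 17))
#' bland_altman(x)
#' @export
bland_altman <- function(x, conf = 0.95, loa_mult = 1.96) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 subjects")
  if (any(!is.finite(x))) stop("x must be complete (no missing cells)")
  d <- x[, 1] - x[, 2]
  m <- (x[, 1] + x[, 2]) / 2
  bias <- mean(d)
  sdd <- sd(d)
  tq <- qt(1 - (1 - conf) / 2, n - 1)
  if (stats::var(m) == 0) {
    slope <- NA_real_; slope_p <- NA_real_
  } else if (sdd == 0) {
    slope <- 0; slope_p <- NA_real_
  } else {
    fit <- lm(d ~ m)
    sm <- suppressWarnings(summary(fit))$coefficients
    slope <- sm[2, 1]; slope_p <- sm[2, 4]
  }
  structure(list(bias = bias,
                 bias_ci_low = bias - tq * sdd / sqrt(n),
                 bias_ci_high = bias + tq * sdd / sqrt(n),
                 sd_diff = sdd,
                 loa_low = bias - loa_mult * sdd,
                 loa_high = bias + loa_mult * sdd,
                 loa_se = sdd * sqrt(3 / n),
                 slope = slope, slope_p = slope_p, n = n),
            class = "ba_result")
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf("bias %.3f [%.3f, %.3f]; LOAs %.3f to %.3f (SE %.3f); slope %.3f (p = %.3g)\n",
              x$bias, x$bias_ci_low, x$bias_ci_high, x$loa_low, x$loa_high,
              x$loa_se, x$slope, x$slope_p))
  invisible(x)
}
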