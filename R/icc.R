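#' Intraclass correlation ICC(A,2): two-way model, absolute agreement,
#' average of k = 2 measurements
#'
#' Computes the average-measures absolute-agreement intraclass correlation
#' from the two-way subjects x sessions mean-square decomposition,
#'
#' \deqn{ICC(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n},}
#'
#' together with the F-based 95% confidence interval (bounds for the
#' single-measures coefficient from the mixed-effects F construction,
#' stepped up to average measures by the Spearman-Brown relation) and the
#' conventional qualitative classification (see [classify_icc()]).
#'
#' @param x numeric matrix with one row per subject and one column per
#'   session/measurement (n >= 3 rows, no missing cells; any k >= 2 columns
#'   is accepted, k = 2 in this design).
#' @param conf confidence level (default 0.95).
#' @return an object of class `icc_result`: list with `estimate`, `ci_low`,
#'   `ci_high`, `n`, `k`, `classification`, `conf`, and the mean squares
#'   `msr`, `msc`, `mse`.
#' @examples
#' x <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
#' icc_a2(x)
#' @export
icc_a2 <- function(x, conf = 0.95) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("x must be complete (no missing cells)")
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("degenerate table: need at least 3 subjects")
  if (k < 2) stop("need at least 2 sessions")
  g <- mean(x); rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - g)^2) / (n - 1)
  msc <- n * sum((cm - g)^2) / (k - 1)
  resid <- x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + g
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  if (sum((x - g)^2) == 0) stop("degenerate table: zero total variance")
  est1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  estk <- (msr - mse) / (msr + (msc - mse) / n)
  # Spearman-Brown step-up from single to average measures; the transform has
  # a pole at -1/(k-1), so single-measures bounds at or below it map to the
  # lower limit of the average-measures parameter space.
  sb <- function(r) if (r <= -1 / (k - 1)) -1 else r * k / (1 + (k - 1) * r)
  if (mse == 0 && msc == 0) {
    # perfect agreement: estimate exactly 1, a point interval
    lo <- hi <- 1
  } else {
    alpha <- 1 - conf
    a <- k * est1 / (n * (1 - est1))
    b <- 1 + k * est1 * (n - 1) / (n * (1 - est1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lo <- sb(n * (msr - fl * mse) /
               (fl * (k * msc + (k * n - k - n) * mse) + n * msr))
    hi <- sb(n * (fu * msr - mse) /
               (k * msc + (k * n - k - n) * mse + n * fu * msr))
    lo <- min(lo, estk)
    hi <- min(max(hi, estk), 1)
  }
  structure(list(estimate = estk, ci_low = lo, ci_high = hi,
                 n = n, k = k, classification = classify_icc(estk),
                 conf = conf, msr = msr, msc = msc, mse = mse),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,%d) = %.3f [%.3f, %.3f] (n = %d, %s)\n",
              x$k, x$estimate, x$ci_low, x$ci_high, x$n, x$classification))
  invisible(x)
}

#' Qualitative classification of an ICC estimate
#'
#' Excellent above 0.80, good above 0.60, moderate above 0.40, poor at or
#' below 0.40. The printed class bounds overlap at 0.40/0.60/0.80; boundary
#' values are assigned to the lower class, consistent with "excellent" being
#' strictly above 0.80.
#'
#' @param estimate numeric vector of ICC estimates.
#' @return character vector in `{"excellent", "good", "moderate", "poor"}`.
#' @examples
#' classify_icc(c(0.85, 0.8, 0.39))
#' @export
classify_icc <- function(estimate) {
  ifelse(estimate > 0.80, "excellent",
         ifelse(estimate > 0.60, "good",
                ifelse(estimate > 0.40, "moderate", "poor")))
}
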