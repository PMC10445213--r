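#' Render an event stream as raw gaze samples
#'
#' Converts a temporally ordered list of fixations (and optional blinks) into
#' a uniformly sampled gaze trace in degrees. Fixations are rendered as their
#' centroid plus isotropic Gaussian jitter; the gaps between consecutive
#' fixations are rendered as raised-cosine position ramps (smooth saccade
#' profiles whose peak velocity exceeds the 30 deg/s detection threshold for
#' amplitudes of about 0.5 deg and above at main-sequence durations). Samples
#' inside blink windows are marked invalid.
#'
#' @param fixations data frame with `onset`, `offset` (ms) and centroid
#'   `x`, `y` (deg); must be ordered and non-overlapping.
#' @param blinks optional data frame with `onset`, `offset` (ms).
#' @param rate_hz sampling rate (default 1000).
#' @param jitter_deg SD of fixational jitter in degrees (0 = noise free).
#' @param seed integer seed for the jitter.
#' @return a data frame with columns `t_ms`, `x`, `y`, `valid` and attribute
#'   `unit = "deg"`.
#' @examples
#' fx <- data.frame(onset = c(0, 1032), offset = c(1000, 1832),
#'                  x = c(0, 5), y = c(0, 0))
#' tr <- generate_raw_samples(fx)
#' nrow(tr)
#' @export
generate_raw_samples <- function(fixations, blinks = NULL, rate_hz = 1000,
                                 jitter_deg = 0, seed = NULL) {
  stopifnot(nrow(fixations) >= 1)
  o <- order(fixations$onset)
  fixations <- fixations[o, ]
  if (any(diff(fixations$onset) <= 0) ||
      any(fixations$offset[-nrow(fixations)] > fixations$onset[-1]))
    stop("fixations must be temporally ordered and non-overlapping")
  if (any(fixations$offset <= fixations$onset))
    stop("fixation offsets must exceed onsets")
  dt <- 1000 / rate_hz
  t <- seq(min(fixations$onset), max(fixations$offset) - dt, by = dt)
  n <- length(t)
  x <- y <- numeric(n)
  for (i in seq_len(nrow(fixations))) {
    inf <- t >= fixations$onset[i] & t < fixations$offset[i]
    x[inf] <- fixations$x[i]; y[inf] <- fixations$y[i]
    if (i < nrow(fixations)) {
      # raised-cosine ramp across the inter-fixation gap
      g0 <- fixations$offset[i]; g1 <- fixations$onset[i + 1]
      ing <- t >= g0 & t < g1
      if (any(ing)) {
        u <- (t[ing] - g0) / (g1 - g0)
        w <- (1 - cos(pi * u)) / 2
        x[ing] <- fixations$x[i] + w * (fixations$x[i + 1] - fixations$x[i])
        y[ing] <- fixations$y[i] + w * (fixations$y[i + 1] - fixations$y[i])
      }
    }
  }
  if (jitter_deg > 0) {
    with_seed(seed, {
      x <- x + rnorm(n, 0, jitter_deg)
      y <- y + rnorm(n, 0, jitter_deg)
    })
  }
  valid <- rep(TRUE, n)
  if (!is.null(blinks) && nrow(blinks))
    for (i in seq_len(nrow(blinks)))
      valid[t >= blinks$onset[i] & t < blinks$offset[i]] <- FALSE
  out <- data.frame(t_ms = t, x = x, y = y, valid = valid)
  attr(out, "unit") <- "deg"
  out
}
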