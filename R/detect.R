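#' Detect fixations, saccades and blinks in a gaze trace
#'
#' Velocity/acceleration event detection in the style of research-grade
#' trackers: samples whose (smoothed) 2-D gaze velocity reaches 30 deg/s or
#' whose absolute acceleration reaches 8000 deg/s^2 form saccade cores;
#' contiguous sub-threshold runs form fixations; runs of invalid samples of at
#' least `blink_min_ms` form blinks (shorter dropouts are linearly
#' interpolated). Fixations and saccades overlapping any blink window extended
#' by `blink_margin_ms` on both sides are removed.
#'
#' Velocity is computed by central finite differences after a moving-average
#' smoother of `smooth_window` samples; acceleration by central differences of
#' the velocity. Saccade cores are extended outward from the threshold
#' crossing while the velocity keeps decreasing monotonically and stays above
#' a small floor (`v_floor`, default 10 deg/s), which recovers the full ramp of a smooth saccade
#' profile instead of only its suprathreshold part and keeps adjacent fixation
#' durations unbiased.
#'
#' @param samples data frame with `t_ms`, `x`, `y` (degrees), `valid`;
#'   uniformly sampled within valid stretches.
#' @param v_threshold saccade velocity threshold in deg/s (default 30).
#' @param a_threshold saccade acceleration threshold in deg/s^2 (default 8000).
#' @param smooth_window moving-average window in samples (odd; default 5;
#'   1 disables smoothing).
#' @param v_floor velocity floor in deg/s for saccade-boundary extension.
#' @param blink_min_ms minimal invalid run counted as a blink (default 10).
#' @param blink_margin_ms exclusion margin around blinks (default 50).
#' @return a list with data frames `fixations` (`onset`, `offset`, `x`, `y`,
#'   `duration`), `saccades` (`onset`, `offset`, `x0`, `y0`, `x1`, `y1`,
#'   `amplitude`, `peak_velocity`) and `blinks` (`onset`, `offset`). Times in
#'   ms; offsets are exclusive (offset = last sample time + sample period).
#' @examples
#' fx <- data.frame(onset = c(0, 1032), offset = c(1000, 1832),
#'                  x = c(0, 5), y = c(0, 0))
#' ev <- detect_events(generate_raw_samples(fx))
#' nrow(ev$saccades)  # the planted 5-degree saccade
#' @export
detect_events <- function(samples, v_threshold = 30, a_threshold = 8000,
                          smooth_window = 5, v_floor = 10,
                          blink_min_ms = 10, blink_margin_ms = 50) {
  empty <- list(
    fixations = data.frame(onset = numeric(0), offset = numeric(0),
                           x = numeric(0), y = numeric(0),
                           duration = numeric(0)),
    saccades = data.frame(onset = numeric(0), offset = numeric(0),
                          x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                          y1 = numeric(0), amplitude = numeric(0),
                          peak_velocity = numeric(0)),
    blinks = data.frame(onset = numeric(0), offset = numeric(0)))
  if (!all(c("t_ms", "x", "y", "valid") %in% names(samples)))
    stop("samples must have columns t_ms, x, y, valid")
  n <- nrow(samples)
  if (n == 0 || !any(samples$valid)) {
    warning("no valid samples; returning empty event lists")
    return(empty)
  }
  if (n < smooth_window + 2)
    stop("trace too short for the velocity-smoothing window")
  t <- samples$t_ms
  dt <- stats::median(diff(t))

  # --- blinks: maximal invalid runs >= blink_min_ms; interpolate shorter ones
  r <- rle(!samples$valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  inv_s <- starts[r$values]; inv_e <- ends[r$values]
  is_blink <- (inv_e - inv_s + 1) * dt >= blink_min_ms
  blinks <- data.frame(onset = t[inv_s[is_blink]],
                       offset = t[inv_e[is_blink]] + dt)
  x <- samples$x; y <- samples$y
  for (i in which(!is_blink)) {  # short dropouts: linear interpolation
    i0 <- max(inv_s[i] - 1, 1); i1 <- min(inv_e[i] + 1, n)
    idx <- inv_s[i]:inv_e[i]
    w <- (t[idx] - t[i0]) / (t[i1] - t[i0])
    x[idx] <- x[i0] + w * (x[i1] - x[i0])
    y[idx] <- y[i0] + w * (y[i1] - y[i0])
  }

  # --- segments of analyzable samples between blinks
  seg_mask <- rep(TRUE, n)
  for (i in which(is_blink)) seg_mask[inv_s[i]:inv_e[i]] <- FALSE
  rs <- rle(seg_mask)
  se <- cumsum(rs$lengths); ss <- se - rs$lengths + 1
  seg <- cbind(ss[rs$values], se[rs$values])

  fix_list <- list(); sac_list <- list()
  for (g in seq_len(nrow(seg))) {
    i0 <- seg[g, 1]; i1 <- seg[g, 2]
    m <- i1 - i0 + 1
    if (m < max(smooth_window + 2, 5)) next
    xs <- x[i0:i1]; ys <- y[i0:i1]; ts <- t[i0:i1]
    if (smooth_window > 1) {
      pad <- (smooth_window - 1) %/% 2
      k <- rep(1 / smooth_window, smooth_window)
      xs <- stats::filter(c(rep(xs[1], pad), xs, rep(xs[m], pad)), k,
                          sides = 2)[(pad + 1):(pad + m)]
      ys <- stats::filter(c(rep(ys[1], pad), ys, rep(ys[m], pad)), k,
                          sides = 2)[(pad + 1):(pad + m)]
    }
    v <- rep(0, m)
    v[2:(m - 1)] <- sqrt((xs[3:m] - xs[1:(m - 2)])^2 +
                         (ys[3:m] - ys[1:(m - 2)])^2) / (2 * dt) * 1000
    a <- rep(0, m)
    a[2:(m - 1)] <- (v[3:m] - v[1:(m - 2)]) / (2 * dt) * 1000
    core <- v >= v_threshold | abs(a) >= a_threshold
    rc <- rle(core)
    ce <- cumsum(rc$lengths); cs <- ce - rc$lengths + 1
    runs <- cbind(cs[rc$values], ce[rc$values])
    in_sacc <- rep(FALSE, m)
    if (nrow(runs)) {
      for (i in seq_len(nrow(runs))) {
        s0 <- runs[i, 1]
        while (s0 > 1 && v[s0 - 1] >= v_floor && v[s0 - 1] < v[s0])
          s0 <- s0 - 1
        e0 <- runs[i, 2]
        while (e0 < m && v[e0 + 1] >= v_floor && v[e0 + 1] < v[e0])
          e0 <- e0 + 1
        runs[i, ] <- c(s0, e0)
      }
      # extension can make neighbouring runs touch; merge overlaps
      keep <- runs[1, , drop = FALSE]
      for (i in seq_len(nrow(runs))[-1]) {
        if (runs[i, 1] <= keep[nrow(keep), 2] + 1)
          keep[nrow(keep), 2] <- max(keep[nrow(keep), 2], runs[i, 2])
        else keep <- rbind(keep, runs[i, ])
      }
      runs <- keep
      sac_list[[length(sac_list) + 1]] <- data.frame(
        onset = ts[runs[, 1]], offset = ts[runs[, 2]] + dt,
        x0 = x[i0 + runs[, 1] - 1], y0 = y[i0 + runs[, 1] - 1],
        x1 = x[i0 + runs[, 2] - 1], y1 = y[i0 + runs[, 2] - 1],
        amplitude = sqrt((x[i0 + runs[, 2] - 1] - x[i0 + runs[, 1] - 1])^2 +
                         (y[i0 + runs[, 2] - 1] - y[i0 + runs[, 1] - 1])^2),
        peak_velocity = vapply(seq_len(nrow(runs)), function(i)
          max(v[runs[i, 1]:runs[i, 2]]), numeric(1)))
      for (i in seq_len(nrow(runs))) in_sacc[runs[i, 1]:runs[i, 2]] <- TRUE
    }
    rf <- rle(!in_sacc)
    fe <- cumsum(rf$lengths); fs <- fe - rf$lengths + 1
    fruns <- cbind(fs[rf$values], fe[rf$values])
    if (nrow(fruns)) {
      fix_list[[length(fix_list) + 1]] <- data.frame(
        onset = ts[fruns[, 1]], offset = ts[fruns[, 2]] + dt,
        x = vapply(seq_len(nrow(fruns)), function(i)
          mean(x[(i0 + fruns[i, 1] - 1):(i0 + fruns[i, 2] - 1)]), numeric(1)),
        y = vapply(seq_len(nrow(fruns)), function(i)
          mean(y[(i0 + fruns[i, 1] - 1):(i0 + fruns[i, 2] - 1)]), numeric(1)))
    }
  }
  fixations <- if (length(fix_list)) do.call(rbind, fix_list) else empty$fixations
  saccades <- if (length(sac_list)) do.call(rbind, sac_list) else empty$saccades
  if (nrow(fixations)) fixations$duration <- fixations$offset - fixations$onset

  # --- blink exclusion: drop events overlapping blink +/- margin
  if (nrow(blinks)) {
    hit <- function(on, off) {
      bad <- rep(FALSE, length(on))
      for (i in seq_len(nrow(blinks)))
        bad <- bad | (on < blinks$offset[i] + blink_margin_ms &
                      off > blinks$onset[i] - blink_margin_ms)
      bad
    }
    if (nrow(fixations))
      fixations <- fixations[!hit(fixations$onset, fixations$offset), ]
    if (nrow(saccades))
      saccades <- saccades[!hit(saccades$onset, saccades$offset), ]
  }
  rownames(fixations) <- rownames(saccades) <- NULL
  list(fixations = fixations, saccades = saccades, blinks = blinks)
}

#' Apply the standard event filters
#'
#' Retains fixations of at least 50 ms and saccades of at least 0.1 deg
#' amplitude (discarding microsaccades), the conventional filters for this
#' task.
#'
#' @param fixations,saccades event data frames as returned by
#'   [detect_events()].
#' @param min_fix_dur_ms minimal fixation duration in ms (default 50).
#' @param min_sacc_amp_deg minimal saccade amplitude in degrees (default 0.1).
#' @return a list with the filtered `fixations` and `saccades`.
#' @export
filter_events <- function(fixations, saccades, min_fix_dur_ms = 50,
                          min_sacc_amp_deg = 0.1) {
  f <- fixations[fixations$duration >= min_fix_dur_ms, , drop = FALSE]
  s <- saccades[saccades$amplitude >= min_sacc_amp_deg, , drop = FALSE]
  rownames(f) <- rownames(s) <- NULL
  list(fixations = f, saccades = s)
}
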