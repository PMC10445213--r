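#' Resolve the current-target timeline from clicks
#'
#' Walks the click stream in time order against the layout: a click is correct
#' if it falls within the circumcircle of the current (lowest not-yet-hit)
#' target, in which case the sequence advances. Misses leave the current
#' target unchanged and do not reset the per-target reaction-time clock.
#'
#' @param clicks data frame with `t`, `x`, `y` (degrees).
#' @param layout a [generate_layout()] result (or a data frame with
#'   `seq_index`, `x`, `y`, `radius`).
#' @return `clicks` augmented with `current` (target index the click was
#'   evaluated against), `correct`, and `accuracy` (1 at the centre, 0 at or
#'   beyond the circumcircle, linear in between).
#' @export
resolve_clicks <- function(clicks, layout) {
  o <- order(clicks$t)
  clicks <- clicks[o, , drop = FALSE]
  cur <- 1L
  nc <- nrow(clicks)
  current <- integer(nc); correct <- logical(nc); accuracy <- numeric(nc)
  for (i in seq_len(nc)) {
    current[i] <- cur
    if (cur > 25L) { correct[i] <- FALSE; accuracy[i] <- 0; next }
    j <- which(layout$seq_index == cur)
    d <- sqrt((clicks$x[i] - layout$x[j])^2 + (clicks$y[i] - layout$y[j])^2)
    accuracy[i] <- click_accuracy(d, layout$radius[j])
    correct[i] <- d <= layout$radius[j]
    if (correct[i]) cur <- cur + 1L
  }
  clicks$current <- current; clicks$correct <- correct
  clicks$accuracy <- accuracy
  clicks
}

#' Relative accuracy of a click
#'
#' `max(0, 1 - d / r)`: 1 for a click exactly at the target centre, 0 for a
#' click at or beyond the circumcircle, linear in between.
#'
#' @param d click-to-centre distance in degrees (vectorized).
#' @param r circumcircle radius in degrees (default 0.675).
#' @return accuracy in \[0, 1\].
#' @export
click_accuracy <- function(d, r = 0.675) pmax(0, 1 - d / r)

#' Trial completion time
#'
#' Time from trial initiation (the click on the central fixation cross) to
#' the first *correct* click on the last target of the sequence, in seconds.
#' `NA` if the last target is never hit.
#'
#' @param trial a `tmt_trial` (see [generate_trial_events()]) or any list with
#'   `clicks`, `layout`, `start_ms`.
#' @return completion time in seconds, or `NA_real_`.
#' @export
completion_time <- function(trial) {
  rc <- resolve_clicks(trial$clicks, trial$layout)
  hit <- rc$correct & rc$current == 25L
  if (!any(hit)) return(NA_real_)
  (min(rc$t[hit]) - trial$start_ms) / 1000
}

#' Speed-accuracy trade-off slope
#'
#' Per correctly hit target, the reaction time is the interval from the
#' previous correct click (trial start for target 1) to the correct click on
#' that target, and the accuracy is the correct click's relative accuracy.
#' Accuracies are clipped to `[eps, 1 - eps]`, transformed to log-odds
#' `log(a / (1 - a))`, and regressed on reaction time by ordinary least
#' squares; the slope (log-odds per ms) is returned. `NA` if fewer than three
#' targets are usable or the reaction times do not vary.
#'
#' @inheritParams completion_time
#' @param eps log-odds clipping bound (default 0.01).
#' @return the OLS slope, or `NA_real_`.
#' @export
speed_accuracy_slope <- function(trial, eps = 0.01) {
  pt <- per_target_rt(trial)
  pt <- pt[!is.na(pt$rt), , drop = FALSE]
  if (nrow(pt) < 3 || stats::var(pt$rt) == 0) return(NA_real_)
  a <- pmin(pmax(pt$accuracy, eps), 1 - eps)
  lo <- log(a / (1 - a))
  unname(coef(lm(lo ~ pt$rt))[2])
}

# Per-target reaction time and accuracy from the resolved click stream.
per_target_rt <- function(trial) {
  rc <- resolve_clicks(trial$clicks, trial$layout)
  hits <- rc[rc$correct, , drop = FALSE]
  out <- data.frame(seq_index = seq_len(25), rt = NA_real_,
                    accuracy = NA_real_, t_click = NA_real_)
  prev <- trial$start_ms
  for (j in seq_len(25)) {
    row <- hits[hits$current == j, , drop = FALSE]
    if (!nrow(row)) break  # sequence never advanced past j - 1
    out$rt[j] <- row$t[1] - prev
    out$accuracy[j] <- row$accuracy[1]
    out$t_click[j] <- row$t[1]
    prev <- row$t[1]
  }
  out
}

#' Assign fixations to targets and label them
#'
#' A fixation falling within `radius` (default 3.25 deg) of at least one
#' target centre is assigned to the nearest such target (exact ties broken by
#' lower sequence index). It is labelled *guiding* if that target is the
#' current target of the sequence at fixation onset, *searching* if it is any
#' other target, and *unassigned* if no target lies within the radius.
#'
#' @param fixations data frame with `onset`, `offset`, `x`, `y`.
#' @param layout the trial layout.
#' @param clicks the trial click stream (defines the current-target timeline).
#' @param radius assignment radius in degrees (default 3.25).
#' @return `fixations` augmented with `object` (assigned `seq_index` or `NA`)
#'   and `label` (`"guiding"`, `"searching"`, `"unassigned"`).
#' @export
assign_fixations <- function(fixations, layout, clicks, radius = 3.25) {
  nf <- nrow(fixations)
  fixations$object <- NA_integer_
  fixations$label <- rep("unassigned", nf)
  if (!nf) return(fixations)
  rc <- resolve_clicks(clicks, layout)
  hit_t <- rep(Inf, 25)  # time each target was first correctly clicked
  for (j in seq_len(25)) {
    h <- rc$t[rc$correct & rc$current == j]
    if (length(h)) hit_t[j] <- h[1]
  }
  ord <- order(layout$seq_index)
  lx <- layout$x[ord]; ly <- layout$y[ord]
  for (i in seq_len(nf)) {
    d <- sqrt((fixations$x[i] - lx)^2 + (fixations$y[i] - ly)^2)
    near <- which(d <= radius)
    if (!length(near)) next
    obj <- near[which.min(d[near])]  # which.min takes the first = lowest index
    fixations$object[i] <- obj
    current <- match(TRUE, hit_t >= fixations$onset[i], nomatch = 26L)
    fixations$label[i] <- if (obj == current) "guiding" else "searching"
  }
  fixations
}

#' Count fixation types
#'
#' @param labeled fixations labelled by [assign_fixations()].
#' @return named integer vector `n_fixations` (all, including unassigned),
#'   `n_guiding`, `n_searching`.
#' @export
count_fixation_types <- function(labeled) {
  c(n_fixations = nrow(labeled),
    n_guiding = sum(labeled$label == "guiding"),
    n_searching = sum(labeled$label == "searching"))
}

#' Median fixation duration and saccade amplitude
#'
#' Sample medians of the (filtered) event streams; the even-count convention
#' is the midpoint of the two central values. `NA` for empty streams.
#'
#' @param fixations,saccades filtered event data frames.
#' @return list with `median_fixation_duration` (ms) and
#'   `median_saccade_amplitude` (deg).
#' @export
summary_stats <- function(fixations, saccades) {
  list(median_fixation_duration =
         if (nrow(fixations)) stats::median(fixations$duration) else NA_real_,
       median_saccade_amplitude =
         if (nrow(saccades)) stats::median(saccades$amplitude) else NA_real_)
}

#' Scanpath length
#'
#' Total angular path covered by the eyes: the sum of Euclidean distances
#' between consecutive fixation centroids (approximately the sum of saccade
#' amplitudes).
#'
#' @param fixations fixation data frame ordered by onset.
#' @return length in degrees (0 for a single fixation).
#' @export
scanpath_length <- function(fixations) {
  if (nrow(fixations) < 2) return(0)
  f <- fixations[order(fixations$onset), ]
  sum(sqrt(diff(f$x)^2 + diff(f$y)^2))
}

#' Eye-hand span
#'
#' Per target with both a correct click and a guiding fixation: the correct
#' click time minus the onset of the first fixation on that target during its
#' episode (positive = the eyes led the hand). A target's episode runs from
#' the correct click on the previous target (trial start for target 1) to
#' `grace_ms` after its own correct click; the grace window makes negative
#' spans representable, where the hand arrives before the eyes and the
#' fixation on the target starts just after the click. The trial value is the
#' median across qualifying targets; targets without a fixation on them in
#' their episode are skipped.
#'
#' @param labeled fixations labelled by [assign_fixations()].
#' @param clicks the trial click stream.
#' @param layout the trial layout.
#' @param use one of `"first"` (default) or `"last"`: which on-target
#'   fixation within the episode anchors the span.
#' @param grace_ms window after the correct click within which a late
#'   on-target fixation still anchors the span (default 200).
#' @return median span in ms, or `NA_real_` if no target qualifies.
#' @export
eye_hand_span <- function(labeled, clicks, layout, use = c("first", "last"),
                          grace_ms = 200) {
  use <- match.arg(use)
  rc <- resolve_clicks(clicks, layout)
  spans <- rep(NA_real_, 25)
  prev <- -Inf
  for (j in seq_len(25)) {
    h <- rc$t[rc$correct & rc$current == j]
    if (!length(h)) break
    g <- labeled$onset[!is.na(labeled$object) & labeled$object == j &
                         labeled$onset > prev &
                         labeled$onset <= h[1] + grace_ms]
    if (length(g))
      spans[j] <- h[1] - if (use == "first") min(g) else max(g)
    prev <- h[1]
  }
  if (all(is.na(spans))) return(NA_real_)
  stats::median(spans, na.rm = TRUE)
}

#' Score one trial
#'
#' Computes all nine per-trial test scores from a trial's (filtered) event and
#' click streams. Scores whose preconditions fail are carried as `NA`.
#'
#' @inheritParams completion_time
#' @param apply_filters apply [filter_events()] to the trial's events before
#'   scoring (default `TRUE`).
#' @param eps log-odds clipping bound for the speed-accuracy slope.
#' @return a one-row data frame with columns `completion_time` (s),
#'   `speed_accuracy_slope` (log-odds per ms), `median_fixation_duration`
#'   (ms), `n_fixations`, `n_guiding`, `n_searching`,
#'   `median_saccade_amplitude` (deg), `eye_hand_span` (ms),
#'   `scanpath_length` (deg).
#' @examples
#' lay <- generate_layout("A", seed = 2)
#' coh <- generate_cohort(sim_config(n_subjects = 2, seed = 2))
#' tr <- generate_trial_events(coh[1, ], lay, "speed", seed = 5)
#' score_trial(tr)
#' @export
score_trial <- function(trial, apply_filters = TRUE, eps = 0.01) {
  fx <- trial$fixations; sc <- trial$saccades
  if (apply_filters) {
    fl <- filter_events(fx, sc)
    fx <- fl$fixations; sc <- fl$saccades
  }
  lab <- assign_fixations(fx, trial$layout, trial$clicks)
  cnt <- count_fixation_types(lab)
  ss <- summary_stats(fx, sc)
  data.frame(
    completion_time = completion_time(trial),
    speed_accuracy_slope = speed_accuracy_slope(trial, eps = eps),
    median_fixation_duration = ss$median_fixation_duration,
    n_fixations = unname(cnt["n_fixations"]),
    n_guiding = unname(cnt["n_guiding"]),
    n_searching = unname(cnt["n_searching"]),
    median_saccade_amplitude = ss$median_saccade_amplitude,
    eye_hand_span = eye_hand_span(lab, trial$clicks, trial$layout),
    scanpath_length = scanpath_length(fx))
}

#' Score every trial of a dataset
#'
#' @param dataset a [generate_dataset()] result.
#' @param ... passed to [score_trial()].
#' @return a data frame with one row per subject x session x part x
#'   instruction x trial and the nine score columns.
#' @export
score_dataset <- function(dataset, ...) {
  idx <- dataset$trials$index
  scores <- do.call(rbind, lapply(dataset$trials$trial, score_trial, ...))
  cbind(idx[, c("subject_id", "session", "part", "instruction", "trial")],
        scores)
}

#' Names of the nine per-trial test scores
#' @return character vector of score column names.
#' @export
score_names <- function() {
  c("completion_time", "speed_accuracy_slope", "median_fixation_duration",
    "n_fixations", "n_guiding", "n_searching", "median_saccade_amplitude",
    "eye_hand_span", "scanpath_length")
}

#' Aggregate trial scores to a subjects-by-sessions condition table
#'
#' For one score in one condition (part x instruction), averages the scored
#' trials per subject and session and returns the n x 2 matrix that is the
#' unit of the reliability analysis. Subjects missing the cell in either
#' session are dropped (with a message).
#'
#' @param scores a [score_dataset()] data frame.
#' @param score one of [score_names()].
#' @param part `"A"` or `"B"`.
#' @param instruction `"speed"` or `"accuracy"`.
#' @return a numeric matrix with one row per retained subject (rownames =
#'   subject ids) and columns `session1`, `session2`.
#' @export
aggregate_condition <- function(scores, score, part, instruction) {
  stopifnot(score %in% names(scores))
  sub <- scores[scores$part == part & scores$instruction == instruction, ]
  if (!nrow(sub)) stop("no trials for condition ", part, "/", instruction)
  cell <- aggregate(sub[[score]],
                    by = list(subject_id = sub$subject_id,
                              session = sub$session),
                    FUN = mean, na.rm = TRUE)
  wide <- merge(cell[cell$session == 1, c("subject_id", "x")],
                cell[cell$session == 2, c("subject_id", "x")],
                by = "subject_id", suffixes = c("1", "2"))
  keep <- is.finite(wide$x1) & is.finite(wide$x2)
  if (any(!keep))
    message(sum(!keep), " subject(s) dropped from ", score, " ", part, "/",
            instruction, " for missing cells")
  wide <- wide[keep, ]
  if (!nrow(wide)) stop("no analyzable data for ", score, " ", part, "/",
                        instruction)
  m <- as.matrix(wide[, c("x1", "x2")])
  dimnames(m) <- list(wide$subject_id, c("session1", "session2"))
  m
}
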