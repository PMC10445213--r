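#' Generate one synthetic trial as an event stream
#'
#' Builds the fixation, saccade and click streams of a single TMT trial with
#' known ground truth. For every target in sequence order the generator plants
#' a number of *searching* fixations on other targets (Poisson count at the
#' subject's rate, or a fixed count), then one *guiding* fixation near the
#' current target, and finally a correct click whose latency after the guiding
#' fixation's onset equals the subject's eye-hand lag plus noise and whose
#' position is Gaussian around the target centre at the subject's dispersion.
#' Clicks that miss the circumcircle are recorded and retried with shrinking
#' dispersion, so misses arise naturally when dispersion is large. Under the
#' accuracy instruction dispersion is scaled down and the lag scaled up.
#'
#' Consecutive fixations are joined by saccade events whose duration follows
#' the main-sequence approximation `2.2 ms/deg x amplitude + 21 ms`.
#'
#' @param traits one row of a [generate_cohort()] data frame (one subject in
#'   one session).
#' @param layout a [generate_layout()] result.
#' @param instruction `"speed"` or `"accuracy"`.
#' @param seed integer seed.
#' @param config a [sim_config()] supplying noise parameters and instruction
#'   factors.
#' @param searching_per_target optional fixed searching-fixation count per
#'   target (overrides the Poisson draw; 0 plants none).
#' @param fix_dur optional fixed fixation duration in ms (overrides the Gamma
#'   draw).
#' @return an object of class `tmt_trial`: a list with elements `part`,
#'   `instruction`, `layout`, `start_ms` (time of the trial-initiating click
#'   on the central fixation cross), `clicks` (`t`, `x`, `y` in degrees),
#'   `fixations`, `saccades`, and `truth` (planted quantities: per-target
#'   searching counts, guiding onsets, lags, click accuracies, scanpath
#'   length, completion time).
#' @export
generate_trial_events <- function(traits, layout,
                                  instruction = c("speed", "accuracy"),
                                  seed = NULL, config = sim_config(),
                                  searching_per_target = NULL,
                                  fix_dur = NULL) {
  instruction <- match.arg(instruction)
  stopifnot(nrow(layout) == 25)
  disp <- traits$click_dispersion
  lag <- traits$eye_hand_lag
  if (instruction == "accuracy") {
    disp <- disp * config$accuracy_dispersion_factor
    lag <- lag * config$accuracy_lag_factor
  }
  with_seed(seed, {
    fx <- fy <- fon <- foff <- numeric(0)
    flab <- character(0); fobj <- integer(0)
    ct <- cx <- cy <- numeric(0)
    lag_true <- guide_on <- acc_true <- rep(NA_real_, 25)
    nsearch <- integer(25)
    t <- 0          # trial initiation: click on the central fixation cross
    pos <- c(0, 0)  # gaze starts at the screen centre

    draw_dur <- function() {
      if (!is.null(fix_dur)) fix_dur
      else max(20, rgamma_mean(1, traits$fix_dur_mean, config$fix_dur_shape))
    }
    travel <- function(from, to) 2.2 * sqrt(sum((to - from)^2)) + 21

    for (j in seq_len(25)) {
      tgt <- c(layout$x[j], layout$y[j])
      ns <- if (!is.null(searching_per_target)) searching_per_target
            else rpois(1, traits$search_rate)
      nsearch[j] <- ns
      for (s in seq_len(ns)) {
        obj <- sample(setdiff(seq_len(25), j), 1)
        ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, 0.4)
        p <- c(layout$x[obj] + rad * cos(ang), layout$y[obj] + rad * sin(ang))
        t <- t + travel(pos, p)
        d <- draw_dur()
        fon <- c(fon, t); foff <- c(foff, t + d)
        fx <- c(fx, p[1]); fy <- c(fy, p[2])
        flab <- c(flab, "searching"); fobj <- c(fobj, obj)
        t <- t + d; pos <- p
      }
      # guiding fixation: within the 3.25 deg assignment radius and closer to
      # the current target than to any other (offsets capped at 0.5 deg)
      off <- rnorm(2, 0, 0.15)
      nrm <- sqrt(sum(off^2))
      if (nrm > 0.45) off <- off * 0.45 / nrm
      p <- tgt + off
      t <- t + travel(pos, p)
      d <- draw_dur()
      g_on <- t
      fon <- c(fon, t); foff <- c(foff, t + d)
      fx <- c(fx, p[1]); fy <- c(fy, p[2])
      flab <- c(flab, "guiding"); fobj <- c(fobj, j)
      t <- t + d; pos <- p
      guide_on[j] <- g_on

      noise <- if (config$lag_noise_sd > 0) rnorm(1, 0, config$lag_noise_sd) else 0
      t_click <- max(g_on + lag + noise,
                     if (length(ct)) max(ct) + 1 else 1)
      lag_true[j] <- t_click - g_on
      dsp <- disp; done <- FALSE
      while (!done) {
        cpos <- tgt + if (dsp > 0) rnorm(2, 0, dsp) else c(0, 0)
        ct <- c(ct, t_click); cx <- c(cx, cpos[1]); cy <- c(cy, cpos[2])
        dist <- sqrt(sum((cpos - tgt)^2))
        if (dist <= layout$radius[j]) {
          acc_true[j] <- 1 - dist / layout$radius[j]
          done <- TRUE
        } else {
          t_click <- t_click + 250
          dsp <- dsp * 0.6  # corrective clicks home in on the target
        }
      }
      t <- max(t, t_click)
    }

    fixations <- data.frame(onset = fon, offset = foff, x = fx, y = fy,
                            duration = foff - fon)
    nf <- nrow(fixations)
    saccades <- if (nf > 1) {
      amp <- sqrt(diff(fx)^2 + diff(fy)^2)
      dur <- 2.2 * amp + 21
      data.frame(onset = foff[-nf], offset = foff[-nf] + dur,
                 x0 = fx[-nf], y0 = fy[-nf], x1 = fx[-1], y1 = fy[-1],
                 amplitude = amp,
                 peak_velocity = pi * amp / (2 * dur) * 1000)
    } else {
      data.frame(onset = numeric(0), offset = numeric(0), x0 = numeric(0),
                 y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
                 amplitude = numeric(0), peak_velocity = numeric(0))
    }
    truth <- list(n_searching = sum(nsearch), n_guiding = 25L,
                  searching_per_target = nsearch,
                  guiding_onset = guide_on, eye_hand_lag = lag_true,
                  click_accuracy = acc_true,
                  fixation_label = flab, fixation_object = fobj,
                  scanpath_length = if (nf > 1) sum(sqrt(diff(fx)^2 + diff(fy)^2)) else 0,
                  completion_time = ct[length(ct)] / 1000)
    structure(list(part = attr(layout, "part"), instruction = instruction,
                   layout = layout, start_ms = 0,
                   clicks = data.frame(t = ct, x = cx, y = cy),
                   fixations = fixations, saccades = saccades, truth = truth),
              class = "tmt_trial")
  })
}

#' Generate a full two-session synthetic dataset
#'
#' Runs the whole study design: every subject performs, in each of two
#' sessions, `trials_per_condition` scored trials per crossing of test half
#' (A, B) and instruction (speed, accuracy) -- 8 scored trials per session at
#' the default of 2. Target layouts are drawn once per trial slot and reused
#' in session two (mirroring a retest with identical spatial arrangements);
#' the instruction order is randomized per subject within each half and kept
#' identical across sessions. Training trials are not simulated, as they
#' contribute no scores.
#'
#' @param config a [sim_config()].
#' @param geometry a [screen_geometry()] used for the layouts.
#' @return an object of class `tmt_dataset`: a list with `cohort`, `layouts`
#'   (one per part x slot), and `trials`, a data-frame-like index with one
#'   `tmt_trial` per row in `trials$trial`.
#' @examples
#' ds <- generate_dataset(sim_config(n_subjects = 2, seed = 3))
#' length(ds$trials$trial)  # 2 subjects x 2 sessions x 8 trials
#' @export
generate_dataset <- function(config = sim_config(),
                             geometry = screen_geometry()) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- generate_cohort(config)
  tpc <- config$trials_per_condition
  slots <- 2L * tpc  # per part: tpc speed + tpc accuracy trials
  layouts <- list()
  for (part in c("A", "B"))
    for (s in seq_len(slots))
      layouts[[paste0(part, s)]] <-
        generate_layout(part, geometry,
                        seed = child_seed(config$seed, 7, match(part, c("A", "B")), s))

  meta <- list(); trials <- list(); k <- 0L
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("S%03d", i)
    # instruction order per subject, fixed across sessions
    order_by_part <- lapply(c(A = 1, B = 2), function(p)
      with_seed(child_seed(config$seed, 11, i, p),
                sample(rep(c("speed", "accuracy"), each = tpc))))
    for (sess in 1:2) {
      traits <- cohort[cohort$subject_id == sid & cohort$session == sess, ]
      for (part in c("A", "B")) {
        instr <- order_by_part[[part]]
        for (s in seq_len(slots)) {
          k <- k + 1L
          trials[[k]] <- generate_trial_events(
            traits, layouts[[paste0(part, s)]], instr[s],
            seed = child_seed(config$seed, 13, i, sess,
                              match(part, c("A", "B")), s),
            config = config)
          meta[[k]] <- data.frame(subject_id = sid, session = sess,
                                  part = part, instruction = instr[s],
                                  trial = s, stringsAsFactors = FALSE)
        }
      }
    }
  }
  idx <- do.call(rbind, meta)
  idx$trial_id <- seq_len(k)
  structure(list(cohort = cohort, layouts = layouts,
                 trials = list(index = idx, trial = trials)),
            class = "tmt_dataset")
}
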