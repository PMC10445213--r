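# Shared fixtures for the test suite; everything is built in code.

# A simple two-fixation trace with one planted saccade of given amplitude.
# Returns the trace plus the planted event table.
planted_saccade_trace <- function(amplitude = 5, fix1 = 1000, fix2 = 800,
                                  jitter = 0, seed = 1, blinks = NULL) {
  sacc_dur <- round(2.2 * amplitude + 21)
  fx <- data.frame(onset = c(0, fix1 + sacc_dur),
                   offset = c(fix1, fix1 + sacc_dur + fix2),
                   x = c(0, amplitude), y = c(0, 0))
  list(trace = generate_raw_samples(fx, blinks = blinks, jitter_deg = jitter,
                                    seed = seed),
       fixations = fx, sacc_dur = sacc_dur)
}

# A minimal hand-built trial: targets on a horizontal line, one guiding
# fixation and one correct click per target, constant eye-hand lag.
line_trial <- function(n_targets = 25, lag = 800, fix_dur = 200,
                       step_ms = 2000, part = "A") {
  layout <- data.frame(label = tmt_labels(part), seq_index = seq_len(25),
                       x = (seq_len(25) - 13) * 4, y = 0, radius = 0.675)
  attr(layout, "part") <- part
  on <- (seq_len(n_targets) - 1) * step_ms + 100
  fixations <- data.frame(onset = on, offset = on + fix_dur,
                          x = layout$x[seq_len(n_targets)],
                          y = layout$y[seq_len(n_targets)],
                          duration = fix_dur)
  clicks <- data.frame(t = on + lag, x = layout$x[seq_len(n_targets)],
                       y = layout$y[seq_len(n_targets)])
  list(part = part, instruction = "speed", layout = layout, start_ms = 0,
       clicks = clicks, fixations = fixations,
       saccades = data.frame(onset = numeric(0), offset = numeric(0),
                             x0 = numeric(0), y0 = numeric(0),
                             x1 = numeric(0), y1 = numeric(0),
                             amplitude = numeric(0),
                             peak_velocity = numeric(0)))
}

# Independent ICC(A,2) oracle: mean squares from stats::aov on the long
# two-way layout, plugged into the average-agreement definition.
icc_a2_aov_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  long <- data.frame(y = as.vector(x),
                     subject = factor(rep(seq_len(n), times = k)),
                     session = factor(rep(seq_len(k), each = n)))
  ms <- unname(summary(stats::aov(y ~ subject + session,
                                  data = long))[[1]][, "Mean Sq"])
  (ms[1] - ms[3]) / (ms[1] + (ms[2] - ms[3]) / n)
}

# Population ICC(A,2) implied by a between-session correlation (equal
# moments): the Spearman-Brown step-up of the pair correlation.
sb2 <- function(rho) 2 * rho / (1 + rho)
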