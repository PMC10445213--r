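#' Simulation configuration
#'
#' Bundles every parameter of the synthetic two-session TMT study. The
#' defaults emulate the study design the package targets: 31 subjects, two
#' sessions, two test halves (A, B), speed and accuracy instructions, two
#' scored trials per condition, and latent subject traits whose session-1 /
#' session-2 values are correlated at `true_icc`.
#'
#' Trait defaults (mean, between-subject SD) are chosen to match the order of
#' magnitude of published descriptive statistics for healthy adults in this
#' task: mean fixation duration 175 (15) ms, searching fixations per target
#' 4.9 (1.1), eye-hand lag 1000 (250) ms, click dispersion 0.25 (0.06) deg.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param true_icc between-session correlation of every latent trait, in
#'   \[0, 1\]; per-trait overrides via `trait_iccs`.
#' @param trials_per_condition scored trials per part x instruction cell
#'   (default 2).
#' @param seed integer master seed; all child streams derive from it.
#' @param trait_means,trait_sds named numeric vectors over the traits
#'   `fix_dur_mean`, `search_rate`, `eye_hand_lag`, `click_dispersion`.
#' @param trait_iccs optional named vector overriding `true_icc` per trait.
#' @param accuracy_dispersion_factor multiplier on click dispersion under the
#'   accuracy instruction (< 1: more precise clicks).
#' @param accuracy_lag_factor multiplier on the eye-hand lag under the
#'   accuracy instruction (> 1: longer spans).
#' @param lag_noise_sd SD (ms) of the per-target noise added to the eye-hand
#'   lag; 0 gives noise-free spans.
#' @param fix_dur_shape Gamma shape of fixation durations (mean set per
#'   subject).
#' @param jitter_deg SD (deg) of fixational jitter when rendering raw samples.
#' @param rate_hz sampling rate used when rendering raw samples.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 31, true_icc = 0.8,
                       trials_per_condition = 2, seed = 1,
                       trait_means = c(fix_dur_mean = 175, search_rate = 4.9,
                                       eye_hand_lag = 1000,
                                       click_dispersion = 0.25),
                       trait_sds = c(fix_dur_mean = 15, search_rate = 1.1,
                                     eye_hand_lag = 250,
                                     click_dispersion = 0.06),
                       trait_iccs = NULL,
                       accuracy_dispersion_factor = 0.5,
                       accuracy_lag_factor = 1.5,
                       lag_noise_sd = 30,
                       fix_dur_shape = 8,
                       jitter_deg = 0.01,
                       rate_hz = 1000) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (true_icc < 0 || true_icc > 1) stop("true_icc must lie in [0, 1]")
  if (trials_per_condition < 1) stop("trials_per_condition must be >= 1")
  need <- c("fix_dur_mean", "search_rate", "eye_hand_lag", "click_dispersion")
  if (!all(need %in% names(trait_means)) || !all(need %in% names(trait_sds)))
    stop("trait_means and trait_sds must name all of: ",
         paste(need, collapse = ", "))
  if (any(trait_sds < 0)) stop("trait SDs must be >= 0")
  iccs <- rep(true_icc, length(need)); names(iccs) <- need
  if (!is.null(trait_iccs)) {
    if (any(trait_iccs < 0 | trait_iccs > 1))
      stop("trait_iccs must lie in [0, 1]")
    iccs[names(trait_iccs)] <- trait_iccs
  }
  structure(list(n_subjects = n_subjects, true_icc = true_icc,
                 trials_per_condition = trials_per_condition, seed = seed,
                 trait_means = trait_means[need], trait_sds = trait_sds[need],
                 trait_iccs = iccs,
                 accuracy_dispersion_factor = accuracy_dispersion_factor,
                 accuracy_lag_factor = accuracy_lag_factor,
                 lag_noise_sd = lag_noise_sd,
                 fix_dur_shape = fix_dur_shape,
                 jitter_deg = jitter_deg, rate_hz = rate_hz),
            class = "sim_config")
}

# Trait floors: keep physically meaningful ranges. At the default means/SDs
# every floor sits >= 3 SD below the mean, so truncation is negligible.
.trait_floors <- c(fix_dur_mean = 60, search_rate = 0.1,
                   eye_hand_lag = 50, click_dispersion = 0.005)

#' Generate a synthetic subject cohort
#'
#' Draws, for each latent trait, a bivariate-normal pair of session-1 and
#' session-2 values per subject with equal means and variances and
#' between-session correlation equal to the trait's configured ICC. Values are
#' floored at a small positive bound per trait (negligible at the default
#' parameters).
#'
#' @param config a [sim_config()].
#' @return a data frame of class `tmt_cohort` with columns `subject_id`,
#'   `session` and one column per trait; `config` is attached as an attribute.
#' @examples
#' coh <- generate_cohort(sim_config(n_subjects = 4, seed = 7))
#' head(coh)
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  with_seed(child_seed(config$seed, 101), {
    out <- data.frame(
      subject_id = rep(sprintf("S%03d", seq_len(n)), times = 2),
      session = rep(1:2, each = n),
      stringsAsFactors = FALSE)
    for (tr in names(config$trait_means)) {
      rho <- config$trait_iccs[[tr]]
      z1 <- rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
      v <- config$trait_means[[tr]] + config$trait_sds[[tr]] * c(z1, z2)
      out[[tr]] <- pmax(v, .trait_floors[[tr]])
    }
    structure(out, config = config, class = c("tmt_cohort", "data.frame"))
  })
}
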