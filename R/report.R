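#' Test-retest reliability report across scores and conditions
#'
#' Builds the full results table of the reliability analysis: one row per
#' score x part x instruction with descriptive statistics per session,
#' Bland-Altman bias (with CI), limits of agreement (with SE), proportional
#' -bias slope (with p-value and significance stars), and ICC(A,2) with CI and
#' qualitative classification.
#'
#' @param scores a [score_dataset()] data frame (per-trial rows).
#' @param scores_use which scores to report (default all nine).
#' @param conf confidence level (default 0.95).
#' @return a data frame of class `tmt_reliability` with one row per score and
#'   condition.
#' @export
reliability_report <- function(scores, scores_use = score_names(),
                               conf = 0.95) {
  if (is.null(scores) || !nrow(scores)) stop("no scores to report")
  rows <- list()
  for (sc in scores_use) {
    for (part in c("A", "B")) {
      for (instr in c("speed", "accuracy")) {
        tab <- tryCatch(aggregate_condition(scores, sc, part, instr),
                        error = function(e) NULL)
        if (is.null(tab) || nrow(tab) < 3) {
          rows[[length(rows) + 1]] <- data.frame(
            score = sc, part = part, instruction = instr, n = if (is.null(tab)) 0L else nrow(tab),
            mean1 = NA, sd1 = NA, mean2 = NA, sd2 = NA, bias = NA,
            bias_ci_low = NA, bias_ci_high = NA, loa_low = NA, loa_high = NA,
            loa_se = NA, slope = NA, slope_p = NA, slope_sig = "",
            icc = NA, icc_ci_low = NA, icc_ci_high = NA,
            icc_class = NA_character_, stringsAsFactors = FALSE)
          next
        }
        ba <- bland_altman(tab, conf = conf)
        ic <- tryCatch(icc_a2(tab, conf = conf), error = function(e) NULL)
        rows[[length(rows) + 1]] <- data.frame(
          score = sc, part = part, instruction = instr, n = nrow(tab),
          mean1 = mean(tab[, 1]), sd1 = sd(tab[, 1]),
          mean2 = mean(tab[, 2]), sd2 = sd(tab[, 2]),
          bias = ba$bias, bias_ci_low = ba$bias_ci_low,
          bias_ci_high = ba$bias_ci_high,
          loa_low = ba$loa_low, loa_high = ba$loa_high, loa_se = ba$loa_se,
          slope = ba$slope, slope_p = ba$slope_p,
          slope_sig = sig_stars(ba$slope_p),
          icc = if (is.null(ic)) NA else ic$estimate,
          icc_ci_low = if (is.null(ic)) NA else ic$ci_low,
          icc_ci_high = if (is.null(ic)) NA else ic$ci_high,
          icc_class = if (is.null(ic)) NA_character_ else ic$classification,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tmt_reliability", "data.frame")
  out
}

# Significance stars at the conventional 0.05 / 0.01 / 0.001 levels.
sig_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}
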