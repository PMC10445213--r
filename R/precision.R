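#' Simulate a population of paired session scores
#'
#' Draws `size` individuals whose two session scores follow a bivariate
#' normal distribution with equal means, equal variances, and correlation
#' `true_icc`. With equal moments, the absolute-agreement intraclass
#' correlation coincides with the pair correlation in expectation, so the
#' population ICC is `true_icc`.
#'
#' @param true_icc population ICC in \[0, 1).
#' @param size population size (default 100000).
#' @param seed integer seed.
#' @param mean,sd common mean and SD of both sessions.
#' @return a `size` x 2 numeric matrix.
#' @export
simulate_population <- function(true_icc, size = 100000, seed = NULL,
                                mean = 0, sd = 1) {
  if (true_icc < 0 || true_icc >= 1) stop("true_icc must lie in [0, 1)")
  with_seed(seed, {
    z1 <- rnorm(size)
    z2 <- true_icc * z1 + sqrt(1 - true_icc^2) * rnorm(size)
    cbind(session1 = mean + sd * z1, session2 = mean + sd * z2)
  })
}

#' Expected ICC confidence-interval bounds at a given sample size
#'
#' Monte-Carlo precision study: from a fixed population with known ICC,
#' repeatedly draw `n` individuals without replacement, compute the F-based
#' 95% CI of ICC(A,2) on each subsample, and aggregate the bounds across
#' replicates. The default aggregation is the mean lower and mean upper bound;
#' alternatives are the median bounds or the 2.5/97.5 percentiles of the
#' point estimates.
#'
#' @param true_icc population ICC in \[0, 1).
#' @param n subsample size (>= 3, <= `population_size`).
#' @param reps number of replicates (default 10000).
#' @param population_size population size (default 100000).
#' @param seed integer seed.
#' @param aggregation `"mean_bounds"` (default), `"median_bounds"`, or
#'   `"percentile_of_estimates"`.
#' @param conf confidence level of the per-replicate interval.
#' @param regenerate_population draw a fresh population each replicate
#'   (default `FALSE`: one fixed population, as in the subsampling design).
#' @return an object of class `precision_result`: list with `true_icc`, `n`,
#'   `ci_low`, `ci_high`, `reps_used`, `redrawn` (degenerate subsamples that
#'   were redrawn), and `aggregation`.
#' @examples
#' precision_ci(0.8, n = 31, reps = 200, seed = 1)
#' @export
precision_ci <- function(true_icc, n, reps = 10000,
                         population_size = 100000, seed = NULL,
                         aggregation = c("mean_bounds", "median_bounds",
                                         "percentile_of_estimates"),
                         conf = 0.95, regenerate_population = FALSE) {
  aggregation <- match.arg(aggregation)
  if (n < 3 || n > population_size) stop("need 3 <= n <= population_size")
  if (reps < 1) stop("reps must be >= 1")
  pop <- simulate_population(true_icc, population_size,
                             seed = child_seed(seed, 1))
  with_seed(child_seed(seed, 2), {
    lo <- hi <- est <- numeric(reps)
    redrawn <- 0L
    for (r in seq_len(reps)) {
      repeat {
        idx <- sample.int(population_size, n)
        if (regenerate_population)
          pop <- simulate_population(true_icc, population_size)
        res <- tryCatch(icc_a2(pop[idx, , drop = FALSE], conf = conf),
                        error = function(e) NULL)
        if (!is.null(res)) break
        redrawn <- redrawn + 1L
      }
      lo[r] <- res$ci_low; hi[r] <- res$ci_high; est[r] <- res$estimate
    }
    bounds <- switch(aggregation,
      mean_bounds = c(mean(lo), mean(hi)),
      median_bounds = c(stats::median(lo), stats::median(hi)),
      percentile_of_estimates =
        unname(quantile(est, c((1 - conf) / 2, 1 - (1 - conf) / 2))))
    structure(list(true_icc = true_icc, n = n, ci_low = bounds[1],
                   ci_high = bounds[2], reps_used = reps, redrawn = redrawn,
                   aggregation = aggregation),
              class = "precision_result")
  })
}

#' @export
print.precision_result <- function(x, ...) {
  cat(sprintf("true ICC %.2f, n = %d: expected 95%% CI %.2f-%.2f (%d reps)\n",
              x$true_icc, x$n, x$ci_low, x$ci_high, x$reps_used))
  invisible(x)
}

#' Precision table over a grid of population ICCs and sample sizes
#'
#' Runs [precision_ci()] for every combination of `true_iccs` and `ns` and
#' returns the results as a table (the study grid is ICC 0.4/0.6/0.8 at
#' n = 31 and 34).
#'
#' @param true_iccs vector of population ICCs.
#' @param ns vector of sample sizes.
#' @inheritParams precision_ci
#' @return a data frame with columns `true_icc`, `n`, `ci_low`, `ci_high`,
#'   `reps`.
#' @export
precision_table <- function(true_iccs = c(0.4, 0.6, 0.8), ns = c(31, 34),
                            reps = 10000, population_size = 100000,
                            seed = NULL, ...) {
  grid <- expand.grid(n = ns, true_icc = true_iccs)[, 2:1]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- precision_ci(grid$true_icc[i], grid$n[i], reps = reps,
                      population_size = population_size,
                      seed = child_seed(seed, i), ...)
    data.frame(true_icc = r$true_icc, n = r$n, ci_low = r$ci_low,
               ci_high = r$ci_high, reps = r$reps_used)
  })
  do.call(rbind, rows)
}
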