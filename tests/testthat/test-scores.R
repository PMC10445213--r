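test_that("completion time runs from trial start to the first correct hit on 25", {
  tr <- line_trial()
  tr$start_ms <- 1000
  tr$clicks <- data.frame(t = c(2000, 36000), x = tr$layout$x[c(1, 25)],
                          y = tr$layout$y[c(1, 25)])
  # only targets 1 and 25 are clicked: the sequence stalls at target 2
  expect_true(is.na(completion_time(tr)))
  # full sequence, with a miss on 25 before the hit
  tr2 <- line_trial()
  tr2$start_ms <- 1000
  hit_t <- seq(2000, by = 1400, length.out = 24)
  tr2$clicks <- data.frame(t = c(hit_t, 35000, 36000),
                           x = c(tr2$layout$x[1:24], tr2$layout$x[25] + 5,
                                 tr2$layout$x[25]),
                           y = 0)
  expect_equal(completion_time(tr2), 35.0)
})

test_that("click accuracy is linear from centre to circumcircle", {
  expect_equal(click_accuracy(0), 1)
  expect_equal(click_accuracy(0.675), 0)
  expect_equal(click_accuracy(1.2), 0)
  expect_equal(click_accuracy(0.675 / 2), 0.5)
})

test_that("speed-accuracy slope matches closed-form OLS on planted data", {
  # log-odds(accuracy) = 0.001 * RT exactly -> slope 0.001
  tr <- line_trial()
  rts <- seq(600, 3000, length.out = 25)
  acc <- stats::plogis(0.001 * rts)
  d <- acc * 0.675  # place clicks at the distance giving accuracy 1 - d/r
  tr$clicks <- data.frame(t = cumsum(rts), x = tr$layout$x + 0.675 - d, y = 0)
  expect_equal(speed_accuracy_slope(tr, eps = 1e-9), 0.001, tolerance = 1e-9)

  # constant accuracy -> slope 0
  tr2 <- line_trial()
  tr2$clicks <- data.frame(t = cumsum(rts), x = tr2$layout$x + 0.3, y = 0)
  expect_equal(speed_accuracy_slope(tr2), 0)

  # random data: agrees with the direct covariance/variance ratio
  set.seed(31)
  tr3 <- line_trial()
  rts3 <- runif(25, 500, 3000)
  d3 <- runif(25, 0, 0.6)
  tr3$clicks <- data.frame(t = cumsum(rts3), x = tr3$layout$x + d3, y = 0)
  a3 <- pmin(pmax(1 - d3 / 0.675, 0.01), 0.99)
  lo3 <- log(a3 / (1 - a3))
  oracle <- sum((rts3 - mean(rts3)) * (lo3 - mean(lo3))) /
    sum((rts3 - mean(rts3))^2)
  expect_equal(speed_accuracy_slope(tr3), oracle, tolerance = 1e-10)

  # too few usable targets or zero RT variance -> undefined
  tr4 <- line_trial()
  tr4$clicks <- data.frame(t = c(500, 900), x = tr4$layout$x[1:2], y = 0)
  expect_true(is.na(speed_accuracy_slope(tr4)))
})

test_that("fixations are assigned to the nearest target within 3.25 deg", {
  tr <- line_trial()  # targets 4 deg apart; clicks at onset + 800
  fx <- data.frame(
    onset = c(150, 150, 50000, 200),
    offset = c(250, 250, 50100, 300),
    # 1 deg from target 1 (current); 1 deg from target 3 (future);
    # far from everything; midway-ish but nearest to target 2
    x = c(tr$layout$x[1] + 1, tr$layout$x[3] + 1, 100, tr$layout$x[2] - 1.5),
    y = c(0, 0, 50, 0))
  lab <- assign_fixations(fx, tr$layout, tr$clicks)
  expect_identical(lab$label, c("guiding", "searching", "unassigned",
                                "searching"))
  expect_identical(lab$object, c(1L, 3L, NA_integer_, 2L))
  cnt <- count_fixation_types(lab)
  expect_identical(unname(cnt), c(4L, 1L, 2L))
})

test_that("fixation-type counts include unassigned fixations in the total", {
  lab <- data.frame(label = c(rep("guiding", 10), rep("searching", 90),
                              rep("unassigned", 5)))
  expect_identical(unname(count_fixation_types(lab)), c(105L, 10L, 90L))
  expect_identical(unname(count_fixation_types(lab[0, , drop = FALSE])),
                   c(0L, 0L, 0L))
})

test_that("medians follow the midpoint convention and flag empty streams", {
  fx <- data.frame(duration = c(100, 200, 300))
  sc <- data.frame(amplitude = c(1, 2))
  ss <- summary_stats(fx, sc)
  expect_equal(ss$median_fixation_duration, 200)
  expect_equal(ss$median_saccade_amplitude, 1.5)
  ss0 <- summary_stats(fx[0, , drop = FALSE], sc[0, , drop = FALSE])
  expect_true(is.na(ss0$median_fixation_duration))
  expect_true(is.na(ss0$median_saccade_amplitude))
})

test_that("scanpath length sums consecutive centroid distances", {
  expect_equal(scanpath_length(data.frame(onset = 1, x = 3, y = 9)), 0)
  fx <- data.frame(onset = c(1, 2), x = c(0, 3), y = c(0, 4))
  expect_equal(scanpath_length(fx), 5)
  set.seed(17)
  fx2 <- data.frame(onset = 1:40, x = rnorm(40, 0, 5), y = rnorm(40, 0, 5))
  brute <- 0
  for (i in 2:40) brute <- brute +
    sqrt((fx2$x[i] - fx2$x[i - 1])^2 + (fx2$y[i] - fx2$y[i - 1])^2)
  expect_equal(scanpath_length(fx2), brute, tolerance = 1e-12)
})

test_that("eye-hand span follows the sign convention (positive = eyes lead)", {
  tr <- line_trial(n_targets = 2, lag = 800)
  lab <- assign_fixations(tr$fixations, tr$layout, tr$clicks)
  expect_equal(eye_hand_span(lab, tr$clicks, tr$layout), 800)
  # hand leads the eye: click at 400 ms, fixation arrives at 500 ms -> -100
  tr2 <- line_trial(n_targets = 1)
  tr2$clicks <- data.frame(t = 400, x = tr2$layout$x[1], y = 0)
  tr2$fixations <- data.frame(onset = 500, offset = 700,
                              x = tr2$layout$x[1], y = 0, duration = 200)
  lab2 <- assign_fixations(tr2$fixations, tr2$layout, tr2$clicks)
  expect_equal(eye_hand_span(lab2, tr2$clicks, tr2$layout), -100)
  # planted constant lag across all 25 targets -> median equals the lag
  tr3 <- line_trial(n_targets = 25, lag = 800)
  lab3 <- assign_fixations(tr3$fixations, tr3$layout, tr3$clicks)
  expect_equal(eye_hand_span(lab3, tr3$clicks, tr3$layout), 800)
})

test_that("score_trial is deterministic and degrades gracefully", {
  cfg <- sim_config(seed = 12)
  coh <- generate_cohort(cfg)
  lay <- generate_layout("A", seed = 12)
  tr <- generate_trial_events(coh[2, ], lay, "speed", seed = 3, config = cfg)
  expect_identical(score_trial(tr), score_trial(tr))
  expect_true(score_trial(tr)$n_guiding + score_trial(tr)$n_searching <=
                score_trial(tr)$n_fixations)
  # no saccades at or above 0.1 deg: amplitude median missing, rest computed
  tr$saccades <- tr$saccades[0, ]
  sc <- score_trial(tr)
  expect_true(is.na(sc$median_saccade_amplitude))
  expect_false(is.na(sc$completion_time))
})

test_that("condition aggregation averages trials and drops incomplete subjects", {
  scores <- data.frame(
    subject_id = rep(c("a", "b", "c"), each = 4),
    session = rep(c(1, 1, 2, 2), times = 3),
    part = "A", instruction = "speed", trial = rep(1:2, times = 6),
    completion_time = c(40, 44, 41, 43,   50, 52, 49, 51,   60, 62, NA, NA))
  tab <- suppressMessages(
    aggregate_condition(scores, "completion_time", "A", "speed"))
  expect_equal(dim(tab), c(2, 2))
  expect_equal(tab["a", ], c(session1 = 42, session2 = 42))
  expect_equal(tab["b", ], c(session1 = 51, session2 = 50))
  # one missing trial: the remaining trial's value stands in
  scores$completion_time[2] <- NA
  tab2 <- suppressMessages(
    aggregate_condition(scores, "completion_time", "A", "speed"))
  expect_equal(unname(tab2["a", 1]), 40)
})
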