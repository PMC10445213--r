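test_that("cohort traits carry the configured between-session correlation", {
  # degenerate case: perfect stability duplicates the session-1 values
  coh1 <- generate_cohort(sim_config(n_subjects = 50, true_icc = 1, seed = 2))
  expect_equal(coh1$fix_dur_mean[coh1$session == 1],
               coh1$fix_dur_mean[coh1$session == 2])
  # sampling-theory bounds on the empirical correlation at n = 10,000
  for (case in list(list(icc = 0, tol = 0.03), list(icc = 0.8, tol = 0.02))) {
    coh <- generate_cohort(sim_config(n_subjects = 10000, true_icc = case$icc,
                                      seed = 3))
    r <- cor(coh$eye_hand_lag[coh$session == 1],
             coh$eye_hand_lag[coh$session == 2])
    expect_lt(abs(r - case$icc), case$tol)
  }
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(true_icc = 1.2), "0, 1")
  expect_error(sim_config(n_subjects = 1), ">= 2")
  expect_error(sim_config(trait_sds = c(fix_dur_mean = -1, search_rate = 1,
                                        eye_hand_lag = 1,
                                        click_dispersion = 1)), ">= 0")
})

test_that("planted event structure is recovered by the scorer", {
  cfg <- sim_config(seed = 8, lag_noise_sd = 0)
  coh <- generate_cohort(cfg)
  lay <- generate_layout("A", seed = 8)
  traits <- coh[1, ]
  traits$eye_hand_lag <- 800
  traits$click_dispersion <- 0  # -> every click accuracy exactly 1
  tr <- generate_trial_events(traits, lay, "speed", seed = 21, config = cfg,
                              searching_per_target = 4)
  sc <- score_trial(tr)
  expect_identical(sc$n_searching, 100L)
  expect_identical(sc$n_guiding, 25L)
  expect_equal(sc$eye_hand_span, 800)
  expect_equal(sc$scanpath_length, tr$truth$scanpath_length)
  expect_equal(sc$completion_time, tr$truth$completion_time)
  expect_true(all(tr$truth$click_accuracy == 1))
  rc <- resolve_clicks(tr$clicks, lay)
  expect_true(all(rc$accuracy[rc$correct] == 1))
})

test_that("trial generation is deterministic in the seed", {
  cfg <- sim_config(seed = 9)
  coh <- generate_cohort(cfg)
  lay <- generate_layout("B", seed = 9)
  a <- generate_trial_events(coh[1, ], lay, "accuracy", seed = 4, config = cfg)
  b <- generate_trial_events(coh[1, ], lay, "accuracy", seed = 4, config = cfg)
  expect_identical(a$fixations, b$fixations)
  expect_identical(a$clicks, b$clicks)
})

test_that("the accuracy instruction tightens clicks and lengthens spans", {
  cfg <- sim_config(seed = 10)
  coh <- generate_cohort(cfg)
  lay <- generate_layout("A", seed = 10)
  acc <- sapply(1:8, function(i) {
    tr <- generate_trial_events(coh[1, ], lay, "accuracy", seed = i,
                                config = cfg)
    c(mean(tr$truth$click_accuracy), score_trial(tr)$eye_hand_span)
  })
  spd <- sapply(1:8, function(i) {
    tr <- generate_trial_events(coh[1, ], lay, "speed", seed = i,
                                config = cfg)
    c(mean(tr$truth$click_accuracy), score_trial(tr)$eye_hand_span)
  })
  expect_gt(mean(acc[1, ]), mean(spd[1, ]))   # higher click accuracy
  expect_gt(mean(acc[2, ]), mean(spd[2, ]))   # longer eye-hand span
})

test_that("datasets realize the full two-session design", {
  ds <- generate_dataset(sim_config(n_subjects = 2, seed = 6))
  idx <- ds$trials$index
  expect_equal(nrow(idx), 2 * 2 * 8)  # subjects x sessions x scored trials
  expect_equal(as.integer(table(idx$part)), c(16L, 16L))
  expect_equal(as.integer(table(idx$instruction)), c(16L, 16L))
  # identical layouts reused across sessions: slot layouts are shared
  expect_length(ds$layouts, 8)
  # instruction order identical across a subject's two sessions
  for (sid in unique(idx$subject_id))
    expect_identical(
      idx$instruction[idx$subject_id == sid & idx$session == 1],
      idx$instruction[idx$subject_id == sid & idx$session == 2])
  # reduced design: one trial per condition -> 4 scored trials per session
  ds1 <- generate_dataset(sim_config(n_subjects = 2, seed = 6,
                                     trials_per_condition = 1))
  expect_equal(nrow(ds1$trials$index), 2 * 2 * 4)
  # determinism
  ds2 <- generate_dataset(sim_config(n_subjects = 2, seed = 6))
  expect_identical(ds$trials$trial[[5]]$clicks, ds2$trials$trial[[5]]$clicks)
})

test_that("raw-sample rendering honours rate, jitter and event ordering", {
  fx <- data.frame(onset = 0, offset = 1000, x = 2, y = -1)
  tr <- generate_raw_samples(fx, rate_hz = 1000, jitter_deg = 0)
  expect_equal(nrow(tr), 1000)
  expect_true(all(tr$x == 2) && all(tr$y == -1))
  bad <- data.frame(onset = c(0, 500), offset = c(600, 900),
                    x = c(0, 1), y = c(0, 0))
  expect_error(generate_raw_samples(bad), "non-overlapping")
})
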