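test_that("ICC(A,2) agrees with an aov-based variance-components oracle", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    x <- matrix(rnorm(2 * n, mean = 10, sd = 2), n, 2)
    x[, 2] <- x[, 2] + 0.8 * (x[, 1] - 10)
    expect_lt(abs(icc_a2(x)$estimate - icc_a2_aov_oracle(x)), 1e-10)
  }
})

test_that("ICC(A,2) point estimate and CI match an independent implementation", {
  # frozen 10 x 2 fixture; reference values computed with an independent
  # published implementation of the two-way absolute-agreement ICC
  s1 <- c(1.370958447147, -0.564698171396, 0.363128411337, 0.632862604961,
          0.404268323141, -0.106124516091, 1.511521997439, -0.094659038413,
          2.018423713877, -0.062714099052)
  s2 <- c(1.106351615963, -0.985942936967, 0.468231210056, 1.350341173059,
          1.530584556831, 0.010478272933, 1.229430706823, -0.647842869487,
          1.94294527713, -0.063897307317)
  res <- icc_a2(cbind(s1, s2))
  expect_equal(res$estimate, 0.9197529863861704, tolerance = 1e-9)
  expect_equal(round(res$ci_low, 2), 0.67)
  expect_equal(round(res$ci_high, 2), 0.98)
  expect_identical(res$classification, "excellent")
})

test_that("perfect agreement yields exactly 1; agreement punishes offsets", {
  x1 <- c(1, 3, 5, 7, 9)
  res <- icc_a2(cbind(x1, x1))
  expect_identical(res$estimate, 1)
  expect_identical(c(res$ci_low, res$ci_high), c(1, 1))
  # constant shift: consistency (Pearson r) stays 1, absolute agreement drops
  res2 <- icc_a2(cbind(x1, x1 + 3))
  expect_lt(res2$estimate, 1)
  expect_equal(cor(x1, x1 + 3), 1)
  # degenerate tables are signalled
  expect_error(icc_a2(cbind(c(1, 2), c(1, 2))), "at least 3")
  expect_error(icc_a2(cbind(rep(2, 5), rep(2, 5))), "zero total variance")
})

test_that("ICC classification follows the published scheme with lower-bound ties", {
  expect_identical(classify_icc(c(0.85, 0.81)), c("excellent", "excellent"))
  expect_identical(classify_icc(c(0.80, 0.7, 0.61)), rep("good", 3))
  expect_identical(classify_icc(c(0.60, 0.5, 0.41)), rep("moderate", 3))
  expect_identical(classify_icc(c(0.40, 0.39, 0)), rep("poor", 3))
})

test_that("Bland-Altman statistics satisfy their defining identities", {
  x1 <- c(10, 12, 15, 19, 24, 30)
  # identical sessions: zero bias, zero-width limits
  ba0 <- bland_altman(cbind(x1, x1))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  # session 1 larger by a constant: positive bias of that constant
  ba2 <- bland_altman(cbind(x1 + 2, x1))
  expect_equal(ba2$bias, 2)
  expect_equal(ba2$sd_diff, 0)
  expect_equal(ba2$slope, 0)
  # LOA identities and the classical SE approximation
  set.seed(5)
  x <- cbind(x1, x1 + rnorm(6))
  ba <- bland_altman(x)
  d <- x[, 1] - x[, 2]
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(ba$loa_se, sd(d) * sqrt(3 / 6))
  expect_equal(ba$bias_ci_low, mean(d) - qt(0.975, 5) * sd(d) / sqrt(6))
  # proportional bias: d = 0.5 * mean exactly
  m <- 1:6
  xp <- cbind(m + 0.25 * m, m - 0.25 * m)
  bap <- bland_altman(xp)
  expect_equal(bap$slope, 0.5, tolerance = 1e-9)
  expect_lt(bap$slope_p, 0.05)
})

test_that("column swap negates bias and slope; ICC is symmetric", {
  set.seed(8)
  x <- cbind(rnorm(12, 50, 5), rnorm(12, 52, 5))
  a <- bland_altman(x); b <- bland_altman(x[, 2:1])
  expect_equal(a$bias, -b$bias)
  expect_equal(a$slope, -b$slope)
  expect_equal(a$sd_diff, b$sd_diff)
  expect_equal(icc_a2(x)$estimate, icc_a2(x[, 2:1])$estimate,
               tolerance = 1e-12)
})

test_that("reliability statistics respect location and scale equivariance", {
  set.seed(9)
  x <- cbind(rnorm(15, 100, 10), rnorm(15, 100, 10))
  a <- list(icc = icc_a2(x), ba = bland_altman(x))
  # adding a constant to both columns changes nothing
  y <- x + 7
  expect_equal(icc_a2(y)$estimate, a$icc$estimate, tolerance = 1e-12)
  expect_equal(bland_altman(y)$bias, a$ba$bias, tolerance = 1e-12)
  expect_equal(bland_altman(y)$slope, a$ba$slope, tolerance = 1e-9)
  # scaling both columns scales bias/LOAs, leaves ICC and slope p unchanged
  z <- x * 3
  expect_equal(icc_a2(z)$estimate, a$icc$estimate, tolerance = 1e-12)
  expect_equal(bland_altman(z)$bias, 3 * a$ba$bias, tolerance = 1e-12)
  expect_equal(bland_altman(z)$loa_high, 3 * a$ba$loa_high, tolerance = 1e-12)
  expect_equal(bland_altman(z)$slope_p, a$ba$slope_p, tolerance = 1e-9)
})

test_that("the reliability report covers all scores and conditions", {
  arts <- suppressMessages(
    run_pipeline(sim_config(n_subjects = 6, seed = 33),
                 stages = c("simulate", "score", "reliability")))
  rep <- arts$report
  expect_s3_class(rep, "tmt_reliability")
  expect_equal(nrow(rep), 9 * 4)
  expect_true(all(score_names() %in% rep$score))
  ok <- !is.na(rep$icc)
  expect_true(any(ok))
  expect_true(all(rep$icc_ci_low[ok] <= rep$icc[ok] + 1e-12))
  expect_true(all(rep$icc[ok] <= rep$icc_ci_high[ok] + 1e-12))
  expect_true(all(rep$loa_low[ok] <= rep$bias[ok] &
                    rep$bias[ok] <= rep$loa_high[ok]))
  expect_error(reliability_report(NULL), "no scores")
})
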