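test_that("one-way ICC matches a hand-computed ANOVA table", {
  # subjects rated (1,2), (2,4), (3,6):
  # row means 1.5, 3, 4.5; grand mean 3
  # MSB = 2 * (1.5^2 + 0 + 1.5^2) / 2 = 4.5/2*2 = 4.5
  # MSW = (0.5^2*6) / 3 = 0.5
  # ICC = (4.5 - 0.5) / (4.5 + 0.5) = 0.8
  res <- icc_oneway(c(1, 2, 3), c(2, 4, 6))
  msb <- 2 * sum((c(1.5, 3, 4.5) - 3)^2) / 2
  msw <- sum((cbind(c(1, 2, 3), c(2, 4, 6)) - c(1.5, 3, 4.5))^2) / 3
  expect_equal(res$ms_between, msb, tolerance = 1e-12)
  expect_equal(res$ms_within, msw, tolerance = 1e-12)
  expect_equal(res$icc, (msb - msw) / (msb + msw), tolerance = 1e-10)
  # Searle F interval, computed by hand from the same mean squares
  f <- msb / msw
  lo <- (f / qf(0.975, 2, 3) - 1) / (f / qf(0.975, 2, 3) + 1)
  hi <- (f * qf(0.975, 3, 2) - 1) / (f * qf(0.975, 3, 2) + 1)
  expect_equal(res$lower, lo, tolerance = 1e-10)
  expect_equal(res$upper, hi, tolerance = 1e-10)
})

test_that("a duplicated rater column gives ICC 1", {
  a <- c(10, 14, 19, 23, 30)
  res <- suppressWarnings(icc_oneway(a, a))
  expect_equal(res$icc, 1)
  expect_warning(icc_oneway(a, a), "within-subject")
})

test_that("ICC Monte-Carlo recovery at the study's variance scale", {
  # between-subject SD 1808 and within-rater SD 1808/sqrt(3) give a true
  # one-way ICC of 0.75 at n = 48 subjects
  set.seed(99)
  est <- replicate(2000, icc_oneway(sim_rating_table(48, 1808, 1808 / sqrt(3)))$icc)
  expect_lt(abs(mean(est) - 0.75), 0.03)
  # noise-free raters drive the ICC to 1
  est0 <- replicate(50, icc_oneway(sim_rating_table(48, 1808, 1))$icc)
  expect_gt(mean(est0), 0.999)
})

test_that("Bland-Altman matches hand computation", {
  # pairs (10,8), (12,9), (11,10): d = 2, 3, 1
  ba <- bland_altman(c(10, 12, 11), c(8, 9, 10))
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_lo, 2 - 1.96, tolerance = 1e-12)
  expect_equal(ba$loa_hi, 2 + 1.96, tolerance = 1e-12)
  expect_equal(ba$ci_bias, 2 + c(-1, 1) * qt(0.975, 2) / sqrt(3),
               tolerance = 1e-12)
  expect_equal(ba$ci_loa_lo, 0.04 + c(-1, 1) * qt(0.975, 2) * sqrt(3 / 3),
               tolerance = 1e-12)
  expect_equal(ba$percent_bias, 100 * 2 / 10, tolerance = 1e-12)
  expect_true(ba$loa_lo <= ba$bias && ba$bias <= ba$loa_hi)

  # identical columns collapse the limits to the bias
  expect_warning(ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3)), "constant")
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_lo, ba0$loa_hi), c(0, 0))
})

test_that("inter-device spacing biases follow from the modality means", {
  # simulated tables whose means match the two modalities' NND summary
  set.seed(21)
  n <- 48
  a <- rnorm(n, 0, 0.6); a <- a - mean(a) + 7.56
  b <- rnorm(n, 0, 0.7); b <- b - mean(b) + 8.45
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, -0.89, tolerance = 1e-10)
})

test_that("percent bias reproduces the printed device difference", {
  expect_equal(round(percent_bias(2661, 12375, 9713), 1), 24.1)
  expect_equal(percent_bias(0, 5, 7), 0)
  expect_equal(percent_bias(2, 11, 9), 20)
  expect_error(percent_bias(1, 1, -1), "undefined")
})

test_that("column swap negates the bias and mirrors the limits; ICC is symmetric", {
  set.seed(4)
  a <- rnorm(30, 100, 10); b <- a * 0.9 + rnorm(30, 0, 4)
  f <- bland_altman(a, b); g <- bland_altman(b, a)
  expect_equal(g$bias, -f$bias)
  expect_equal(g$loa_lo, -f$loa_hi)
  expect_equal(g$loa_hi, -f$loa_lo)
  expect_equal(g$percent_bias, -f$percent_bias)
  expect_equal(icc_oneway(b, a)$icc, icc_oneway(a, b)$icc, tolerance = 1e-12)

  # adding a constant to both columns changes neither bias nor limits
  h <- bland_altman(a + 250, b + 250)
  expect_equal(h$bias, f$bias, tolerance = 1e-9)
  expect_equal(c(h$loa_lo, h$loa_hi), c(f$loa_lo, f$loa_hi), tolerance = 1e-9)
})

test_that("percent bias converges under a symmetric 24% device deficit", {
  set.seed(12)
  n <- 500
  a <- rnorm(n, 12375, 1800)
  b <- a * (2 - 0.24) / (2 + 0.24) + rnorm(n, 0, 300)
  ba <- bland_altman(a, b)
  expect_equal(ba$percent_bias, 24, tolerance = 0.06)
})

test_that("difference-on-covariate regression matches the normal equations", {
  x <- 1:5
  d <- c(2.1, 4.2, 5.9, 8.1, 9.8)  # near 2x
  a <- d; b <- rep(0, 5)
  res <- diff_vs_covariate(a, b, x)
  # hand OLS
  bx <- sum((x - 3) * (d - mean(d))) / sum((x - 3)^2)
  b0 <- mean(d) - bx * 3
  expect_equal(res$slope, bx, tolerance = 1e-10)
  expect_equal(res$intercept, b0, tolerance = 1e-10)
  fit <- d - (b0 + bx * x)
  expect_equal(res$r_squared, 1 - sum(fit^2) / sum((d - mean(d))^2),
               tolerance = 1e-10)

  # perfectly linear differences give r^2 = 1; constant ones slope 0, r^2 0
  perf <- suppressWarnings(diff_vs_covariate(2 * x, rep(0, 5), x))
  expect_equal(perf$r_squared, 1)
  flat <- diff_vs_covariate(rep(4, 5), rep(1, 5), x)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(diff_vs_covariate(d, b, rep(1, 5)), "constant covariate")
})

test_that("detectable difference reproduces the power calculation", {
  dd <- detectable_difference(15528, 1808, 48, power = 0.80, alpha = 0.05)
  expect_gt(dd, 6.6)
  expect_lt(dd, 6.8)
  expect_equal(detectable_difference(100, 0, 48), 0)
  # quadrupling n roughly halves the detectable two-sample difference
  d1 <- detectable_difference(100, 10, 100)
  d4 <- detectable_difference(100, 10, 400)
  expect_equal(d4 / d1, 0.5, tolerance = 0.01)
  # paired design with the same inputs is smaller
  expect_lt(detectable_difference(100, 10, 48, design = "paired"),
            detectable_difference(100, 10, 48))
  expect_error(detectable_difference(100, 10, 48, power = 1.2), "power")
})
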