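test_that("paired_comparison gates between t and Wilcoxon and handles edges", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  same <- paired_comparison(x, x)
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)
  expect_match(same$test, "t-test")

  expect_error(paired_comparison(x + 1, x), "zero variance")
  expect_error(paired_comparison(x, x[-1]), "equal length")

  set.seed(12)
  d <- rnorm(27, 0.5, 1)
  res <- paired_comparison(d, rep(0, 27))
  expect_match(res$test, "t-test")
  expect_lt(abs(res$p_value - sign_flip_p(d)), 0.015)

  # grossly skewed differences should fail the normality gate
  set.seed(13)
  skew <- rexp(40)^3
  res2 <- paired_comparison(skew, rep(0, 40))
  expect_match(res2$test, "wilcoxon")
})

test_that("one_sample_vs_reference matches the t formula", {
  set.seed(3)
  raw <- rnorm(27)
  x <- 0.72 + 0.02 * (raw - mean(raw)) / sd(raw)   # exact mean/sd
  res <- one_sample_vs_reference(x, 0.7382)
  expect_equal(abs(res$t), abs(0.72 - 0.7382) / (0.02 / sqrt(27)))
  # joint rescaling leaves t unchanged
  expect_equal(one_sample_vs_reference(10 * x, 7.382)$t, res$t)

  exact <- one_sample_vs_reference(x, mean(x))
  expect_equal(exact$t, 0)
  expect_error(one_sample_vs_reference(rep(1, 5), 0), "zero variance")
})

test_that("identity_regression matches a normal-equations oracle", {
  set.seed(27)
  xy <- rbvn(27, 0.6)
  y <- 5 + 2 * xy[, 1]; x <- 3 + xy[, 2]
  got <- identity_regression(y, x)
  want <- ols_oracle(y, x)
  expect_equal(got$slope, want$slope, tolerance = 1e-10)
  expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
  expect_equal(got$see, want$see, tolerance = 1e-10)
  expect_equal(got$r, cor(y, x), tolerance = 1e-10)
  expect_true(got$slope_p_vs_1 >= 0 && got$slope_p_vs_1 <= 1)
})

test_that("identity_regression handles exact fits per the identity contract", {
  x <- c(1, 2, 3, 4)
  ident <- identity_regression(x, x)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  expect_equal(ident$r, 1)
  expect_equal(ident$see, 0)
  expect_identical(ident$slope_p_vs_1, 1)
  expect_identical(ident$intercept_p_vs_0, 1)

  doubled <- identity_regression(2 * x, x)
  expect_equal(doubled$slope, 2)
  expect_identical(doubled$slope_p_vs_1, 0)

  shifted <- identity_regression(x + 3.5, x)
  expect_equal(shifted$slope, 1)
  expect_equal(shifted$intercept, 3.5)

  expect_error(identity_regression(x, rep(1, 4)), "zero variance")
})

test_that("r_squared_percent reports rounded explained variance", {
  expect_identical(r_squared_percent(0), 0)
  expect_identical(r_squared_percent(0.60), 36)
  expect_identical(r_squared_percent(0.62), 38)
  expect_identical(r_squared_percent(-0.53), 28)
  expect_error(r_squared_percent(1.2), "\\[-1, 1\\]")
})

test_that("bland_altman matches hand arithmetic and degenerates safely", {
  m <- c(1, 2, 3); d <- c(-1, 0, 1)
  ba <- bland_altman(m + d / 2, m - d / 2)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_lower, -1.96)
  expect_equal(ba$loa_upper, 1.96)
  expect_equal(ba$trend_r, 1)

  x <- c(4, 5, 6, 7)
  expect_warning(same <- bland_altman(x, x), "collapse")
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_lower, same$loa_upper), c(0, 0))
  expect_false(same$trend_computable)
})

test_that("moment_loa is exact on sample moments and at the correlation limits", {
  eq <- moment_loa(1, 2, 1, 2, 1)
  expect_equal(c(eq$bias, eq$loa_lower, eq$loa_upper), c(0, 0, 0))
  anti <- moment_loa(0, 1.5, 0, 2.5, -1)
  expect_equal(anti$sd_diff, 4)

  set.seed(44)
  for (r in c(-0.4, 0.2, 0.8)) {
    xy <- rbvn(40, r)
    a <- 3 + 1.3 * xy[, 1]; b <- 2 + 0.7 * xy[, 2]
    ba <- bland_altman(a, b)
    ml <- moment_loa(mean(a), sd(a), mean(b), sd(b), cor(a, b))
    expect_equal(ba$bias, ml$bias)
    expect_equal(ba$sd_diff, ml$sd_diff)
    expect_equal(ba$loa_lower, ml$loa_lower)
    expect_equal(ba$loa_upper, ml$loa_upper)
    # LOA midpoint is the bias
    expect_equal((ba$loa_lower + ba$loa_upper) / 2, ba$bias)
  }
  expect_error(moment_loa(0, 1, 0, 1, 1.4), "<= 1")
})

test_that("detectable_correlation follows the Fisher-z solution", {
  r27 <- detectable_correlation(27, 0.05, 0.80)
  expect_equal(r27, tanh((qnorm(0.975) + qnorm(0.8)) / sqrt(24)))
  # strictly decreasing in n, increasing in power
  ns <- c(10, 27, 50, 200)
  expect_true(all(diff(sapply(ns, detectable_correlation)) < 0))
  expect_gt(detectable_correlation(27, power = 0.9), r27)
  # at power 0.5 and large n, atanh(r) ~ z_{1-a/2}/sqrt(n-3)
  expect_equal(detectable_correlation(10003, 0.05, 0.5),
               tanh(qnorm(0.975) / 100), tolerance = 1e-12)
  expect_error(detectable_correlation(3), ">= 4")
})

test_that("correlate_differences reports r/p and flags degenerate input", {
  d <- c(0.3, -0.2, 0.5, 0.1, -0.4)
  expect_false(correlate_differences(d, rep(2, 5))$computable)
  self <- correlate_differences(d, d)
  expect_equal(self$r, 1)

  # p-values uniform under the null (KS over 500 replicates)
  set.seed(77)
  p <- replicate(500, correlate_differences(rnorm(20), rnorm(20))$p_value)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("statistics are symmetric under joint negation", {
  set.seed(91)
  xy <- rbvn(30, 0.5)
  a <- 2 + xy[, 1]; b <- 1.5 + 1.2 * xy[, 2]
  ba1 <- bland_altman(a, b); ba2 <- bland_altman(-a, -b)
  expect_equal(abs(ba2$bias), abs(ba1$bias))
  expect_equal(ba2$sd_diff, ba1$sd_diff)
  expect_equal(abs(ba2$trend_r), abs(ba1$trend_r))
  expect_equal(ba2$trend_p, ba1$trend_p)
  r1 <- identity_regression(b, a); r2 <- identity_regression(-b, -a)
  expect_equal(r2$slope, r1$slope)
  expect_equal(abs(r2$intercept), abs(r1$intercept))
  expect_equal(r2$see, r1$see)
})
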