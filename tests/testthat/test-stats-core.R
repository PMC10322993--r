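test_that("Welch t-test from summary statistics matches hand computations", {
  # equal variances: t = -1 / sqrt(2/10), df reduces to 18
  tr <- welch_t(0, 1, 10, 1, 1, 10)
  expect_equal(tr$statistic, -1 / sqrt(2 / 10), tolerance = 1e-12)
  expect_equal(tr$df, 18)
  # identical summaries
  tr0 <- welch_t(5, 2, 12, 5, 2, 12)
  expect_equal(tr0$statistic, 0)
  expect_equal(tr0$p_raw, 1)
  # published full-scale IQ summaries: strongly significant difference
  iq <- welch_t(90.4, 14.53, 30, 109.5, 7.65, 40)
  expect_lt(iq$p_raw, 0.001)
  expect_lt(iq$effect_size, 0)
  expect_error(welch_t(0, 1, 1, 1, 1, 10))
})

test_that("two-sided p from t reproduces printed p-values", {
  expect_equal(round(p_from_t(-4.11, 69), 5), 0.00011)
  expect_equal(round(p_from_t(2.244, 78), 3), 0.028)
  expect_equal(round(p_from_t(-2.58, 13.7), 3), 0.022)
  expect_equal(p_from_t(0, 10), 1)
  expect_error(p_from_t(1, 0))
})

test_that("p from t is symmetric in the sign and decreasing in magnitude", {
  ts <- c(0.3, 0.8, 1.7, 2.9, 4.2)
  for (df in c(3, 13.7, 68)) {
    expect_equal(p_from_t(ts, df), p_from_t(-ts, df))
    expect_true(all(diff(p_from_t(ts, df)) < 0))
  }
})

test_that("Cohen's d uses the pooled-SD formula", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # pooled SD of {0,2} and {1,3} is sqrt(2); difference of means is -1
  expect_equal(cohens_d(c(0, 2), c(1, 3)), -1 / sqrt(2), tolerance = 1e-12)
  set.seed(42)
  expect_equal(cohens_d(rnorm(1e4, 1), rnorm(1e4, 0)), 1, tolerance = 0.05)
  expect_error(cohens_d(c(1, 1), c(1, 1)))
})

test_that("residualize returns exact OLS residuals orthogonal to covariates", {
  # constant covariate is rank deficient with the intercept
  expect_error(residualize(c(1, 2, 3), c(1, 1, 1)))
  x <- 1:4
  expect_equal(residualize(2 * x + 3, x), rep(0, 4), tolerance = 1e-12)
  # hand OLS: slope 1.3, intercept -0.5
  expect_equal(residualize(c(1, 2, 3, 5), x), c(0.2, -0.1, -0.4, 0.3),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:20) {
    cov <- matrix(rnorm(60), 20, 3)
    r <- residualize(rnorm(20), cov)
    expect_lt(max(abs(cor(r, cov))), 1e-10)
  }
})

test_that("ANCOVA group F has the expected df and reduces to pooled t^2", {
  set.seed(11)
  y <- rnorm(70)
  g <- rep(c("a", "b"), c(30, 40))
  covs <- data.frame(age = rnorm(70), sex = rbinom(70, 1, 0.5),
                     global = rnorm(70))
  tr <- ancova_group_effect(y, g, covs)
  expect_equal(tr$df, c(1, 65))
  # constant covariates carry no information: partial F = pooled t squared
  for (i in 1:5) {
    y <- rnorm(30)
    g <- rep(c("a", "b"), c(14, 16))
    f_const <- ancova_group_effect(y, g, data.frame(c1 = rep(3, 30)))
    tt <- t.test(y[g == "a"], y[g == "b"], var.equal = TRUE)
    expect_equal(f_const$statistic, unname(tt$statistic)^2,
                 tolerance = 1e-10)
    expect_equal(f_const$p_raw, tt$p.value, tolerance = 1e-10)
  }
  expect_error(ancova_group_effect(rnorm(5), rep("a", 5), NULL))
})

test_that("ANCOVA p-values are uniform under the null", {
  set.seed(21)
  p <- replicate(400, {
    y <- rnorm(40)
    g <- rep(c("a", "b"), each = 20)
    ancova_group_effect(y, g, data.frame(x = rnorm(40)))$p_raw
  })
  rej <- mean(p < 0.05)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("Pearson correlation handles exact and hand-computed cases", {
  x <- c(0.3, 1.7, 2.2, 5.1)
  expect_equal(pearson_with_p(x, x)$statistic, 1)
  expect_equal(pearson_with_p(x, -x)$statistic, -1)
  tr <- pearson_with_p(c(1, 2, 3), c(1, 2, 4))
  expect_equal(round(tr$statistic, 4), 0.982)
  # pairwise deletion
  tr2 <- pearson_with_p(c(1, 2, 3, NA), c(1, 2, 4, 9))
  expect_equal(tr2$n, 3)
  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)))
})

test_that("Fisher r-to-z reproduces printed z statistics", {
  expect_equal(round(fisher_z_compare(-0.42, 30, 0.23, 40)$statistic, 2),
               -2.69)
  expect_equal(round(fisher_z_compare(-0.37, 29, 0.18, 39)$statistic, 2),
               -2.22)
  tr <- fisher_z_compare(0.5, 20, 0.5, 35)
  expect_equal(tr$statistic, 0)
  expect_equal(tr$p_raw, 1)
  expect_error(fisher_z_compare(1, 10, 0.5, 10))
})

test_that("Fisher comparison is antisymmetric in its arguments", {
  set.seed(3)
  for (i in 1:25) {
    r1 <- runif(1, -0.9, 0.9); r2 <- runif(1, -0.9, 0.9)
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    expect_equal(fisher_z_compare(r1, n1, r2, n2)$statistic,
                 -fisher_z_compare(r2, n2, r1, n1)$statistic,
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.73), 0.73)
  expect_equal(bh_fdr(c(0.001, 0.5)), c(0.002, 0.5))
  p <- c(0.04, 0.01, 0.01, 0.9)
  expect_equal(bh_fdr(p)[2], bh_fdr(p)[3])  # ties stay tied
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.1, 1.2)))
})

test_that("BH adjustment agrees with an independent brute-force oracle", {
  set.seed(99)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_fdr(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
})
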