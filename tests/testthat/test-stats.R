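test_that("identical group summaries give t = 0, p = 1", {
  r <- t_test_from_summary(0.5, 0.1, 10, 0.5, 0.1, 10)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_two_sided, 1)
  rz <- t_test_from_summary(2, 0, 5, 2, 0, 5)
  expect_equal(rz$p_two_sided, 1)  # degenerate equal constants: p = 1
  expect_error(t_test_from_summary(2, 0, 5, 3, 0, 5), "zero variance")
})

test_that("summary-statistic t test equals the raw-sample t test on moment-matched data", {
  set.seed(99)
  for (i in 1:20) {
    n1 <- sample(4:40, 1); n2 <- sample(4:40, 1)
    m1 <- rnorm(1); m2 <- rnorm(1)
    s1 <- runif(1, 0.2, 3); s2 <- runif(1, 0.2, 3)
    x1 <- moment_matched_sample(m1, s1, n1, base = rnorm(n1))
    x2 <- moment_matched_sample(m2, s2, n2, base = rnorm(n2))
    expect_equal(mean(x1), m1, tolerance = 1e-12)
    expect_equal(sd(x1), s1, tolerance = 1e-12)
    for (meth in c("welch", "pooled")) {
      ours <- t_test_from_summary(mean(x1), sd(x1), n1, mean(x2), sd(x2), n2,
                                  method = meth)
      ref <- t.test(x1, x2, var.equal = (meth == "pooled"))
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-10)
      expect_equal(ours$ci_95, unname(as.vector(ref$conf.int)),
                   tolerance = 1e-10)
    }
  }
})

test_that("welch and pooled tests coincide for balanced groups with equal SDs", {
  a <- t_test_from_summary(1.2, 0.4, 12, 0.9, 0.4, 12, method = "welch")
  b <- t_test_from_summary(1.2, 0.4, 12, 0.9, 0.4, 12, method = "pooled")
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$df, b$df)
  expect_equal(a$p_two_sided, b$p_two_sided)
})

test_that("p-value display rounding follows the journal convention", {
  expect_equal(format_p(0.0060), 0.01)
  expect_equal(format_p(0.0411), 0.04)
  expect_equal(format_p(0.639), 0.6)
  expect_equal(format_p(0.513), 0.5)
  expect_equal(format_p(0.0006), 6e-04)
  expect_equal(format_p(0.0035), 0.0035)
})

test_that("Spearman rho matches the classical rank-difference formula on tie-free data", {
  set.seed(7)
  for (i in 1:10) {
    n <- 6
    x <- sample(100, n); y <- sample(100, n)  # tie-free with prob ~1
    if (anyDuplicated(x) || anyDuplicated(y)) next
    d <- rank(x) - rank(y)
    oracle <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
    expect_equal(spearman_cor(x, y)$statistic, oracle, tolerance = 1e-12)
  }
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(11)
  x <- rnorm(30); y <- rnorm(30)
  base <- spearman_cor(x, y)$statistic
  expect_equal(spearman_cor(exp(x), y)$statistic, base)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$statistic, base)
  ## perfect monotone association
  expect_equal(spearman_cor(x, exp(x))$statistic, 1)
  expect_equal(spearman_cor(x, -x^3)$statistic, -1)
})

test_that("Spearman handles missing data pairwise and rejects degenerate input", {
  x <- c(1, 2, 3, 4, NA, 6)
  y <- c(2, 4, 6, 8, 10, NA)
  r <- spearman_cor(x, y)
  expect_equal(r$n, 4)
  expect_equal(r$statistic, 1)
  expect_error(spearman_cor(1:3, 3:1), "4 complete")
  expect_error(spearman_cor(rep(1, 6), 1:6), "constant")
  ## t-approximation p value matches the closed form
  set.seed(3)
  x <- rnorm(12); y <- 0.5 * x + rnorm(12)
  r <- spearman_cor(x, y)
  tval <- r$statistic * sqrt((12 - 2) / (1 - r$statistic^2))
  expect_equal(r$p_two_sided, 2 * pt(-abs(tval), 10), tolerance = 1e-12)
})

test_that("Bland-Altman satisfies its defining identities", {
  ## perfect agreement
  x <- c(1.2, 3.4, 2.2, 5.1)
  r <- bland_altman(x, x)
  expect_equal(r$mean_diff, 0)
  expect_equal(c(r$loa_lower, r$loa_upper), c(0, 0))
  expect_equal(r$r, 1)
  ## constant offset, no spread
  r2 <- bland_altman(x + 0.3, x)
  expect_equal(r2$mean_diff, 0.3)
  expect_equal(c(r2$loa_lower, r2$loa_upper), c(0.3, 0.3))
  ## random pairs: limits are mean +/- 1.96 sd, midpoint is the mean
  set.seed(21)
  a <- rnorm(50); b <- a + rnorm(50, -0.06, 0.03)
  r3 <- bland_altman(a, b)
  d <- a - b
  expect_equal(r3$mean_diff, mean(d))
  expect_equal(r3$sd_diff, sd(d))
  expect_equal(r3$loa_lower, mean(d) - 1.96 * sd(d))
  expect_equal(r3$loa_upper, mean(d) + 1.96 * sd(d))
  expect_equal((r3$loa_lower + r3$loa_upper) / 2, r3$mean_diff)
  expect_error(bland_altman(1, 1), "2 complete")
})

test_that("simulated intra-rater differences reproduce the expected limits of agreement", {
  set.seed(17)
  base <- rnorm(1e4, 2, 0.5)
  second <- base + rnorm(1e4, -0.059, 0.0337)
  r <- bland_altman(second, base)
  ## Monte-Carlo tolerances: ~5 sigma of the n = 1e4 sampling error
  expect_lt(abs(r$mean_diff - (-0.059)), 0.002)
  expect_lt(abs(r$loa_upper - 0.007), 0.004)
  expect_lt(abs(r$loa_lower - (-0.125)), 0.004)
})
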