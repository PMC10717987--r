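test_that("paired t matches the closed form on the (1,2,3) example", {
  r <- paired_t(c(2, 4, 6), c(1, 2, 3))  # differences 1,2,3
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-6)   # 3.4641
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 0.0741799, tolerance = 1e-6)
  # antisymmetry
  r2 <- paired_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p_value, r$p_value)
  expect_error(paired_t(1:4, 1:4), "zero-variance")
  expect_error(paired_t(1:4, 1:3), "equal length")
})

test_that("independent t matches hand computation on integer samples", {
  r <- independent_t(1:5, 2:6, equal_var = TRUE)
  expect_equal(r$statistic, -1, tolerance = 1e-12)
  expect_equal(r$df, 8)
  r0 <- independent_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(independent_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("t-test wrappers agree with closed-form oracles on random inputs", {
  set.seed(41)
  for (rep in 1:200) {
    n <- sample(3:30, 1)
    a <- rnorm(n, sd = runif(1, 0.5, 3))
    b <- rnorm(n, mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    op <- oracle_paired_t(a, b)
    rp <- paired_t(a, b)
    expect_equal(rp$statistic, op$t, tolerance = 1e-9)
    expect_equal(rp$p_value, op$p, tolerance = 1e-9)
    m <- sample(3:30, 1)
    c2 <- rnorm(m, 0.3, 2)
    og <- oracle_pooled_t(a, c2)
    rg <- independent_t(a, c2, equal_var = TRUE)
    expect_equal(rg$statistic, og$t, tolerance = 1e-9)
    expect_equal(rg$p_value, og$p, tolerance = 1e-9)
    ow <- oracle_welch_t(a, c2)
    rw <- independent_t(a, c2, equal_var = FALSE)
    expect_equal(rw$statistic, ow$t, tolerance = 1e-9)
    expect_equal(rw$df, ow$df, tolerance = 1e-9)
    expect_equal(rw$p_value, ow$p, tolerance = 1e-9)
  }
})

test_that("Shapiro-Wilk wrapper reproduces the reference statistic", {
  r <- shapiro_wilk(1:9)
  # value cross-checked against an independent implementation (scipy.stats)
  expect_equal(r$statistic, 0.9722884258803877, tolerance = 1e-9)
  expect_equal(r$p_value, 0.91356095, tolerance = 1e-6)
  expect_error(shapiro_wilk(c(1, 2)), "at least 3")
  expect_error(shapiro_wilk(rep(4, 10)), "zero-variance")
})

test_that("pointwise comparison counts significant points correctly", {
  set.seed(42)
  n_subj <- 9
  base <- matrix(rnorm(n_subj * 101, 0, 1), n_subj)
  # large shift with small i.i.d. jitter: all 101 points significant
  pc <- pointwise_compare(base, base + 10 +
                            matrix(rnorm(n_subj * 101, 0, 0.3), n_subj))
  expect_identical(pc$n_significant_points, 101L)
  # identical curves: zero-variance points counted as non-significant
  pc0 <- pointwise_compare(base, base)
  expect_identical(pc0$n_significant_points, 0L)
  # localized effect in 20-40 % of the cycle
  shift <- matrix(0, n_subj, 101); shift[, 21:41] <- 5
  m2 <- base + shift + matrix(rnorm(n_subj * 101, 0, 0.2), n_subj)
  pc1 <- pointwise_compare(base, m2)
  oracle <- vapply(1:101, function(k)
    oracle_paired_t(base[, k], m2[, k])$p < 0.05, logical(1))
  expect_identical(pc1$significant_mask, oracle)
  expect_identical(pc1$n_significant_points, sum(oracle))
  expect_gte(sum(pc1$significant_mask[21:41]), 20)
  expect_error(pointwise_compare(base, base[1:5, ]), "dimensions")
})

test_that("power search reproduces the noncentral-t sample size", {
  expect_identical(power_n_two_sample(1.37, 0.05, 0.80, tails = 1), 16L)
  # a two-tailed test at the same effect size needs more participants
  expect_gt(power_n_two_sample(1.37, 0.05, 0.80, tails = 2), 16L)
  # boundary: a huge effect needs only the minimum 2 per group
  expect_identical(power_n_two_sample(10, 0.05, 0.80, tails = 1), 4L)
  expect_error(power_n_two_sample(-1), "d must be")
  expect_error(power_n_two_sample(0.5, alpha = 1.2), "alpha")
})

test_that("required N is monotone in effect size, alpha and power", {
  n_by_d <- vapply(c(0.3, 0.5, 0.8, 1.37), function(d)
    power_n_two_sample(d, 0.05, 0.8, tails = 2), integer(1))
  expect_true(all(diff(n_by_d) <= 0))
  n_by_a <- vapply(c(0.01, 0.05, 0.1), function(a)
    power_n_two_sample(0.8, a, 0.8, tails = 2), integer(1))
  expect_true(all(diff(n_by_a) <= 0))
  n_by_p <- vapply(c(0.7, 0.8, 0.9, 0.95), function(p)
    power_n_two_sample(0.8, 0.05, p, tails = 2), integer(1))
  expect_true(all(diff(n_by_p) >= 0))
})
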