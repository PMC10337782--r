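test_that("pearson matches the direct product-moment formula", {
  set.seed(51)
  for (i in 1:5) {
    x <- rnorm(20); y <- rnorm(20) + 0.5 * x
    res <- pearson_cor(x, y)
    # brute-force covariance / sigma oracle
    r_direct <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res$r, r_direct, tolerance = 1e-12)
    # two-sided p from the t transform with n - 2 df
    tt <- r_direct * sqrt((20 - 2) / (1 - r_direct^2))
    expect_equal(res$p_value, 2 * pt(-abs(tt), df = 18), tolerance = 1e-10)
  }
})

test_that("perfect correlations are labelled strong in absolute value", {
  x <- 1:10 + 0
  up <- pearson_cor(x, x)
  dn <- pearson_cor(x, -x)
  expect_equal(up$r, 1)
  expect_equal(dn$r, -1)
  expect_equal(up$strength, "STRONG")
  expect_equal(dn$strength, "STRONG")   # banding uses |r|
  expect_error(pearson_cor(x, rep(3, 10)), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
})

test_that("strength bands cover [0, 1] with boundaries in the moderate band", {
  expect_equal(correlation_strength(0.29), "WEAK")
  expect_equal(correlation_strength(0.3), "MODERATE")
  expect_equal(correlation_strength(0.7), "MODERATE")
  expect_equal(correlation_strength(0.71), "STRONG")
  expect_equal(correlation_strength(-0.519), "MODERATE")
  expect_equal(correlation_strength(-0.916), "STRONG")
})

test_that("Student's t-test matches the textbook formula", {
  set.seed(52)
  x <- rnorm(15, 1); y <- rnorm(12, 0.5)
  p <- two_sample_t(x, y)
  sp2 <- ((15 - 1) * var(x) + (12 - 1) * var(y)) / (15 + 12 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 15 + 1 / 12))
  expect_equal(p, 2 * pt(-abs(tt), df = 25), tolerance = 1e-10)

  expect_equal(two_sample_t(1:10 + 0, 1:10 + 0), 1.0)
  big <- rnorm(50, 10, 1)
  expect_lt(two_sample_t(big, rnorm(50, 0, 1)), 1e-10)
})

test_that("Bland-Altman reports mean, sample SD and 1.96 limits", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  same <- bland_altman(a, b)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$sd_difference, 0)
  expect_equal(same$n_beyond_threshold, 0)

  # hand-computed: diffs {+2, -2} -> mean 0, sd sqrt(8) = 2.8284,
  # limits +/- 1.96 * 2.8284 = 5.5437
  ba <- bland_altman(c(12, 8), c(10, 10))
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96 * 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1.96 * 2 * sqrt(2), tolerance = 1e-12)

  set.seed(53)
  u <- rnorm(30, 50, 5); v <- rnorm(30, 50, 5)
  expect_equal(bland_altman(u, v)$mean_difference,
               -bland_altman(v, u)$mean_difference, tolerance = 1e-12)
  expect_true(bland_altman(u, v)$loa_low <= bland_altman(u, v)$mean_difference)
})

test_that("pearson is invariant under affine maps, sign flips with negative scale", {
  set.seed(54)
  x <- rnorm(25); y <- rnorm(25) + x
  r0 <- pearson_cor(x, y)$r
  expect_equal(pearson_cor(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_cor(x, -2 * y + 1)$r, -r0, tolerance = 1e-12)
})
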