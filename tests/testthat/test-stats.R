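# statistical procedures: t-test, normality, age adjustment, regression,
# ANCOVA, percent differences, multivariable models, ICC

test_that("pooled t-test matches the hand-computed example", {
  tt <- group_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3.674, tolerance = 1e-3)
  expect_equal(tt$p, 0.0214, tolerance = 2e-2)
  expect_equal(group_t_test(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(group_t_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_silent(group_t_test(rnorm(5), rnorm(9)))  # unequal n is fine
  expect_error(group_t_test(1, c(1, 2)), "n >= 2")
})

test_that("D'Agostino-Pearson matches frozen reference values and detects skew", {
  # frozen oracle values from an independent implementation of the same
  # omnibus statistic (scipy.stats.normaltest on identical data)
  x <- sin(1:40) * 2 + (1:40) * 0.1
  r <- dagostino_pearson(x)
  expect_equal(r$k2, 1.0812997150, tolerance = 1e-9)
  expect_equal(r$p, 0.5823696721, tolerance = 1e-9)
  y <- (1:20)^2 / 10
  r2 <- dagostino_pearson(y)
  expect_equal(r2$k2, 2.5146974324, tolerance = 1e-9)

  expect_error(dagostino_pearson(rnorm(5)), "n >= 20")

  # behaviour under the null and a skewed alternative
  pn <- vapply(1:20, function(s)
    withr::with_seed(s, dagostino_pearson(rnorm(5000))$p), numeric(1))
  expect_gte(mean(pn > 0.05), 0.90)
  pe <- withr::with_seed(1, dagostino_pearson(stats::rexp(5000))$p)
  expect_lt(pe, 0.001)
})

test_that("age adjustment recenters values on the target age per group", {
  # all donors already at 65 -> unchanged
  d <- data.frame(age = rep(65, 6), sex = rep(0:1, 3), v = rnorm(6))
  expect_equal(age_adjust(d, "v")$v, d$v, ignore_attr = TRUE)

  # perfectly linear value = 2 * age -> all adjusted to 130
  d2 <- data.frame(age = c(60, 70, 80, 60, 70, 80), sex = rep(0, 6))
  d2$v <- 2 * d2$age
  expect_equal(age_adjust(d2, "v")$v, rep(130, 6), ignore_attr = TRUE)

  # a known age slope is removed: adjusted values uncorrelated with age
  d3 <- withr::with_seed(5, data.frame(age = runif(300, 30, 90),
                                       sex = rep(0:1, 150)))
  d3$v <- 100 - 0.8 * d3$age + withr::with_seed(6, rnorm(300, 0, 5))
  adj <- age_adjust(d3, "v")
  fit <- summary(lm(adj$v ~ adj$age))$coefficients
  expect_lt(abs(fit[2, 1]), 2 * fit[2, 2])
  expect_error(age_adjust(data.frame(age = 1:2, sex = 0, v = 1:2), "v"),
               "n < 3")
})

test_that("linear regression matches closed-form OLS", {
  f <- linear_fit(c(0, 1, 2, 3), c(1, 3, 5, 7))   # exact line y = 2x + 1
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  f2 <- linear_fit(c(0, 1, 2), c(0, 1, 3))
  expect_equal(f2$slope, 1.5)
  expect_equal(f2$intercept, -1 / 6)
  expect_error(linear_fit(c(0, 1), c(1, 2)), "n >= 3")
  expect_error(linear_fit(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("percent-of-mean difference reproduces every printed elevation pair", {
  pairs <- list(c(3773, 4272, 12.4), c(3586, 4629, 25.4), c(3561, 4606, 25.6),
                c(3429, 4790, 33.1), c(3262, 5042, 42.9))
  for (p in pairs)
    expect_equal(round(pct_difference(p[1], p[2]), 1), p[3])
  expect_equal(pct_difference(10, 10), 0)
  expect_error(pct_difference(-1, 5), "positive")
})

test_that("ANCOVA: identical groups, injected offset, slope difference", {
  x <- rep(seq(0, 10, length.out = 30), 2)
  g <- rep(c("f", "m"), each = 30)
  y0 <- withr::with_seed(8, 3 * x + rnorm(60, 0, 1))
  an0 <- ancova_compare(x, y0, g)
  # same data in both groups -> no slope or elevation difference signal
  y_same <- rep(y0[1:30], 2)
  an_same <- ancova_compare(x, y_same, g)
  expect_equal(an_same$elevation_diff, 0, tolerance = 1e-10)
  expect_equal(an_same$pct_diff, 0, tolerance = 1e-10)

  # injected elevation offset of 1045 with matched x
  y1 <- y0 + ifelse(g == "m", 1045, 0) * 1
  an1 <- ancova_compare(x, y1, g)
  se <- diff(an1$elevation_diff_ci) / (2 * qt(0.975, df = 57))
  expect_lt(abs(an1$elevation_diff - 1045), 2 * se)
  expect_lt(an1$elevation_p, 0.001)
  expect_gt(an1$slope_p, 0.05)

  # different slopes are detected
  x2 <- rep(seq(0, 10, length.out = 200), 2)
  g2 <- rep(c("f", "m"), each = 200)
  y2 <- withr::with_seed(9,
    ifelse(g2 == "m", 2, 1) * x2 + rnorm(400, 0, 1))
  expect_lt(ancova_compare(x2, y2, g2)$slope_p, 0.01)

  expect_error(ancova_compare(c(1, 1, 1, 2, 3, 4), rnorm(6),
                              rep(c("a", "b"), each = 3)), "zero x-variance")
})

test_that("midpoint shifting changes intercepts but not slopes or R2", {
  withr::with_seed(10, {
    x <- runif(40, 5, 15); y <- 2 * x + rnorm(40)
  })
  f0 <- linear_fit(x, y)
  fs <- linear_fit(x - (min(x) + max(x)) / 2, y)
  expect_equal(fs$slope, f0$slope)
  expect_equal(fs$r2, f0$r2)
  expect_false(isTRUE(all.equal(fs$intercept, f0$intercept)))
})

test_that("multivariable fit: orthogonal VIFs, collinearity loop, recovery", {
  # mutually orthogonal predictors -> all VIF = 1
  X <- data.frame(a = rep(c(-1, 1), 8), b = rep(c(-1, -1, 1, 1), 4),
                  c = rep(c(-1, 1), each = 8))
  y <- withr::with_seed(11, 1 + 2 * X$a - X$b + rnorm(16, 0, 0.5))
  m <- multivariable_fit(y, X)
  expect_equal(m$terms$vif, rep(1, 3))
  expect_equal(sign(m$terms$std_beta), sign(m$terms$b))

  # duplicated predictor is flagged and removed by the VIF loop
  X2 <- cbind(X, a_dup = X$a)
  m2 <- multivariable_fit(y, X2)
  expect_length(m2$removed, 1)
  expect_equal(nrow(m2$terms), 3)
  expect_true(all(is.finite(m2$terms$vif)))

  # coefficients recovered from a generated model
  withr::with_seed(12, {
    X3 <- data.frame(u = rnorm(500), v = rnorm(500))
    y3 <- 5 + 3 * X3$u - 2 * X3$v + rnorm(500, 0, 0.3)
  })
  m3 <- multivariable_fit(y3, X3)
  expect_equal(m3$terms$b, c(3, -2), tolerance = 0.05)
  expect_error(multivariable_fit(rnorm(3), X3[1:3, ]), "exceed")
})

test_that("ICC(2,1) matches the frozen reference and its null behaviour", {
  # frozen oracle from an independent two-way absolute-agreement
  # implementation (pingouin ICC(A,1) on identical data)
  m <- matrix(c(9.1, 9.3, 9.0, 7.2, 7.5, 7.1, 8.1, 8.0, 8.3,
                6.0, 6.2, 6.1, 7.9, 8.1, 8.0, 6.5, 6.4, 6.6),
              nrow = 6, byrow = TRUE)
  r <- icc21(m)
  expect_equal(r$icc, 0.984368, tolerance = 1e-5)
  expect_true(r$lo < r$icc && r$icc < r$hi)
  expect_lt(r$lo, 0.95)

  # identical columns -> ICC = 1
  ident <- matrix(rep(rnorm(10), 3), 10, 3)
  expect_equal(icc21(ident)$icc, 1)

  # independent random columns -> ICC near 0
  z <- vapply(1:30, function(s)
    withr::with_seed(100 + s, icc21(matrix(rnorm(300), 100, 3))$icc),
    numeric(1))
  expect_lt(abs(mean(z)), 2 * sd(z) / sqrt(30))

  expect_error(icc21(matrix(1, 3, 2)), "n >= 5")
  mm <- matrix(rnorm(12), 6, 2); mm[1, 1] <- NA
  expect_error(icc21(mm), "missing")
})

test_that("repeated VOI extraction with sub-voxel jitter is highly reliable", {
  r <- voi_reliability_icc(n_phantoms = 6, k = 3, jitter_mm = 0.1,
                           voxel_size_mm = 0.25, seed = 14)
  expect_gt(r$icc_area$icc, 0.99)
  expect_gt(r$icc_bmc$icc, 0.99)
})
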