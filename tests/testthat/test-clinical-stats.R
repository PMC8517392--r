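test_that("pooled t reproduces printed two-group statistics from summaries", {
  cases <- list(
    # n1, mean1, sd1, n2, mean2, sd2, expected t (NC first)
    age  = c(50, 46.88, 10.60, 50, 50.20, 9.73, -1.632),
    sbp  = c(50, 118.84, 3.94, 50, 120.68, 6.00, -1.813),
    dbp  = c(50, 77.70, 6.31, 50, 79.24, 7.40, -1.120),
    pp   = c(50, 41.14, 7.13, 50, 41.44, 8.85, -0.187),
    hr   = c(50, 67.82, 8.37, 50, 71.02, 9.41, -1.797),
    lad  = c(50, 33.38, 3.46, 50, 34.62, 3.45, -1.795),
    lvedv = c(50, 98.00, 12.58, 50, 96.80, 10.68, 0.514),
    gwi  = c(50, 1899.84, 173.47, 50, 1712.80, 249.44, 4.353),
    gcw  = c(50, 2151.08, 196.17, 50, 1934.58, 266.64, 4.625)
  )
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    res <- t_from_summary(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    # printed statistics carry 3 decimals; inputs are themselves rounded, so
    # agreement is asserted to within half a unit in the last printed place
    expect_lt(abs(res$statistic - cs[7]), 1e-3, label = nm)
    expect_identical(res$df, 98)
    expect_true(res$p_value >= 0 && res$p_value <= 1)
  }
})

test_that("raw-sample t equals the summary t on the samples' own moments", {
  set.seed(1)
  x1 <- with_moments(stats::rnorm(50), 46.88, 10.60)
  x2 <- with_moments(stats::rnorm(50, 2, 3), 50.20, 9.73)
  raw <- t_from_raw(x1, x2)
  summ <- t_from_summary(50, mean(x1), stats::sd(x1), 50, mean(x2), stats::sd(x2))
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-9)
  expect_equal(round(raw$statistic, 3), -1.632)
  # cross-check against the stats package
  expect_equal(raw$statistic,
               unname(stats::t.test(x1, x2, var.equal = TRUE)$statistic),
               tolerance = 1e-9)
  # antisymmetry and degenerate equality
  expect_equal(t_from_raw(x2, x1)$statistic, -raw$statistic, tolerance = 1e-12)
  same <- t_from_raw(x1, x1)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-9)
})

test_that("Mann-Whitney U matches exhaustive pair counting", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(res$U, 0)
  expect_lt(res$statistic, 0)

  x <- c(3, 1, 4, 1, 5)
  same <- mann_whitney(x, x)
  expect_equal(same$U, length(x)^2 / 2)
  expect_identical(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(2)
  for (n1 in c(2, 4, 8)) for (n2 in c(3, 5, 8)) {
    x1 <- sample(1:6, n1, replace = TRUE)  # ties included
    x2 <- sample(1:6, n2, replace = TRUE)
    expect_equal(mann_whitney(x1, x2)$U, brute_force_u(x1, x2), info = paste(n1, n2))
    # cross-check U against the stats package W statistic
    expect_equal(mann_whitney(x1, x2)$U,
                 unname(suppressWarnings(stats::wilcox.test(x1, x2)$statistic)))
  }
})

test_that("Mann-Whitney Z sign follows the group-1-first convention", {
  set.seed(3)
  lo <- stats::rnorm(30, 0); hi <- stats::rnorm(30, 2)
  expect_lt(mann_whitney(lo, hi)$statistic, 0)
  expect_gt(mann_whitney(hi, lo)$statistic, 0)
  expect_equal(mann_whitney(lo, hi)$statistic, -mann_whitney(hi, lo)$statistic,
               tolerance = 1e-12)
})

test_that("chi-square without continuity correction reproduces printed values", {
  expect_equal(round(chi_square_2x2(29, 21, 26, 24)$statistic, 3), 0.364)
  expect_equal(round(chi_square_2x2(12, 38, 14, 36)$statistic, 3), 0.208)
  expect_identical(chi_square_2x2(10, 10, 20, 20)$statistic, 0)
  # invariance under transposition of rows and columns
  a <- chi_square_2x2(29, 21, 26, 24)
  b <- chi_square_2x2(24, 26, 21, 29)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  # cross-check against the stats package
  m <- matrix(c(29, 26, 21, 24), 2)
  expect_equal(a$statistic,
               unname(stats::chisq.test(m, correct = FALSE)$statistic),
               tolerance = 1e-9)
  expect_error(chi_square_2x2(0, 0, 5, 5), "margins")
})

test_that("Pearson correlation handles exact linear relations", {
  x <- 1:20
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 20)), "degenerate")
})

test_that("univariable standardized coefficient equals the correlation", {
  set.seed(4)
  x <- stats::rnorm(200)
  y <- 1.7 * x + stats::rnorm(200)
  fit <- ols_standardized(y, data.frame(x = x))
  expect_equal(fit$beta_std, pearson_r(x, y)$r, tolerance = 1e-9)
  # perfect fit
  f2 <- suppressWarnings(ols_standardized(x, data.frame(x = x)))
  expect_equal(f2$beta_std, 1, tolerance = 1e-12)
  expect_equal(f2$r_squared, 1, tolerance = 1e-12)
  # null model at large n
  y0 <- stats::rnorm(1000)
  X0 <- data.frame(a = stats::rnorm(1000), b = stats::rnorm(1000))
  expect_lt(ols_standardized(y0, X0)$r_squared, 0.02)
  expect_error(ols_standardized(y, data.frame(x = x, x2 = 2 * x)), "collinearity")
})

test_that("stepwise selection finds the true predictor on an orthogonal design", {
  set.seed(5)
  n <- 500
  X <- as.data.frame(qr.Q(qr(matrix(stats::rnorm(n * 4), n))) * sqrt(n))
  names(X) <- paste0("x", 1:4)
  y <- 0.5 * X$x2 + stats::rnorm(n)
  sel <- stepwise_select(y, X, p_enter = 0.01, p_remove = 0.02)
  expect_identical(sel$predictors, "x2")
  expect_lt(abs(sel$beta_std - pearson_r(X$x2, y)$r), 1e-9)

  # all-null candidates with a strict entry threshold: empty model
  empty <- stepwise_select(stats::rnorm(n), X, p_enter = 1e-9, p_remove = 1e-8)
  expect_true(empty$selected_none)
  expect_identical(empty$r_squared, 0)

  # permissive thresholds admit every candidate
  full <- stepwise_select(y, X, p_enter = 1, p_remove = 1)
  expect_setequal(full$predictors, names(X))
  expect_error(stepwise_select(y, X, p_enter = 0.2, p_remove = 0.1), "p_enter")
})

test_that("Bland-Altman bias and limits follow their definitions", {
  m1 <- c(30, 35, 40, 45)
  expect_identical(bland_altman(m1, m1)$bias, 0)
  expect_identical(bland_altman(m1, m1)$loa_low, 0)
  shift <- bland_altman(m1, m1 + 5)
  expect_identical(shift$bias, 5)
  expect_identical(shift$loa_low, 5)
  expect_identical(shift$loa_high, 5)
  # swap symmetry
  set.seed(6)
  a <- stats::rnorm(20, 36, 15); b <- a + stats::rnorm(20, 3, 4)
  ab <- bland_altman(a, b); ba <- bland_altman(b, a)
  expect_equal(ab$bias, -ba$bias, tolerance = 1e-12)
  expect_equal(ab$loa_low, -ba$loa_high, tolerance = 1e-12)
  expect_lte(ab$loa_low, ab$bias)
  expect_equal(ab$loa_high - ab$bias, ab$bias - ab$loa_low, tolerance = 1e-12)
  expect_error(bland_altman(a, b[-1]), "equal length")
})
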