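test_that("major-axis fit recovers exact lines to machine precision", {
  mu <- seq(0.02, 0.28, length.out = 12)
  fit <- fit_major_axis(mu, 0.32 + 8.0 * mu, interval_method = "none")
  expect_equal(fit$b, 8.0, tolerance = 1e-12)
  expect_equal(fit$rm, 0.32, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("major-axis slope is symmetric under axis exchange", {
  set.seed(41)
  for (i in 1:10) {
    x <- runif(15); y <- 1.5 * x + rnorm(15, 0, 0.3)
    fxy <- suppressWarnings(fit_major_axis(x, y, interval_method = "none"))
    fyx <- suppressWarnings(fit_major_axis(y, x, interval_method = "none"))
    expect_equal(fxy$b * fyx$b, 1, tolerance = 1e-9)
  }
})

test_that("major-axis fit matches the perpendicular-distance oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- runif(n)
    y <- runif(1, 0.5, 3) * x + rnorm(n, 0, 0.4)
    fit <- suppressWarnings(fit_major_axis(x, y, interval_method = "none"))
    oracle <- oracle_major_axis(x, y)
    expect_equal(fit$rm, unname(oracle["rm"]), tolerance = 1e-6)
    expect_equal(fit$b, unname(oracle["b"]), tolerance = 1e-6)
  }
})

test_that("undefined or degenerate fits are reported as errors", {
  # symmetric cloud: zero covariance
  x <- c(-1, 1, 0, 0); y <- c(0, 0, -1, 1)
  expect_error(fit_major_axis(x, y), "undefined")
  expect_error(fit_major_axis(1:2, 1:2), "3 samples")
  expect_error(fit_major_axis(rep(1, 5), rnorm(5)), "all equal")
  expect_error(fit_quadratic(rep(1, 5), rnorm(5)), "all equal")
})

test_that("quadratic fit recovers exact curves and handles constant data", {
  mu <- seq(0.02, 0.28, length.out = 12)
  fit <- fit_quadratic(mu, 0.58 + 28.7 * mu^2, n_boot = 0)
  expect_equal(fit$rm, 0.58, tolerance = 1e-12)
  expect_equal(fit$b, 28.7, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  flat <- fit_quadratic(mu, rep(0.7, 12), n_boot = 0)
  expect_equal(flat$rm, 0.7, tolerance = 1e-12)
  expect_equal(flat$b, 0, tolerance = 1e-12)
})

test_that("noiseless synthetic transects are recovered by both fitters", {
  tx <- simulate_transect(n_samples = 22, form = "linear", residual_sd = 0,
                          seed = 43)
  fit <- fit_major_axis(tx$true_mu, tx$true_r_sb, interval_method = "none")
  expect_equal(fit$rm, 0.32, tolerance = 1e-8)
  expect_equal(fit$b, 8.0, tolerance = 1e-8)

  txq <- simulate_transect(n_samples = 22, form = "quadratic", residual_sd = 0,
                           seed = 43)
  fitq <- fit_quadratic(txq$true_mu, txq$true_r_sb, n_boot = 0)
  expect_equal(fitq$rm, 0.58, tolerance = 1e-8)
  expect_equal(fitq$b, 28.7, tolerance = 1e-8)
})

test_that("OLS attenuates relative to the major axis on errors-in-variables data", {
  set.seed(44)
  for (i in 1:10) {
    n <- 40
    x_true <- runif(n)
    x <- x_true + rnorm(n, 0, 0.2)
    y <- 2 * x_true + rnorm(n, 0, 0.2)
    ma <- suppressWarnings(fit_major_axis(x, y, interval_method = "none"))
    ols <- coef(lm(y ~ x))[[2]]
    expect_lte(abs(ols), abs(ma$b) + 1e-12)
  }
})

test_that("bootstrap intervals are seeded, ordered and reproducible", {
  tx <- simulate_transect(n_samples = 22, form = "quadratic", seed = 45)
  f1 <- fit_quadratic(tx$true_mu, tx$true_r_sb, n_boot = 200, seed = 9)
  f2 <- fit_quadratic(tx$true_mu, tx$true_r_sb, n_boot = 200, seed = 9)
  expect_identical(f1$rm_interval, f2$rm_interval)
  expect_lt(f1$rm_interval[1], f1$rm_interval[2])
  expect_error(fit_quadratic(tx$true_mu, tx$true_r_sb, n_boot = 100),
               "seed")
  expect_error(fit_major_axis(tx$true_mu, tx$true_r_sb), "seed")
})

test_that("the analytic major-axis interval brackets the estimate", {
  tx <- simulate_transect(n_samples = 22, form = "linear", seed = 46)
  fit <- fit_major_axis(tx$true_mu, tx$true_r_sb,
                        interval_method = "major-axis-analytic")
  expect_lt(fit$b_interval[1], fit$b)
  expect_gt(fit$b_interval[2], fit$b)
  expect_lt(fit$rm_interval[1], fit$rm)
  expect_gt(fit$rm_interval[2], fit$rm)
})

test_that("negative fitted intercepts are reported with a warning, not clamped", {
  # steep line crossing below zero near the origin
  x <- c(0.1, 0.2, 0.3, 0.4)
  y <- 10 * x - 0.5
  expect_warning(fit <- fit_major_axis(x, y, interval_method = "none"),
                 "negative")
  expect_lt(fit$rm, 0)
})

test_that("prediction and maintenance fraction follow the model algebra", {
  lin <- pirt_fit("linear", 0.32, 8.0)
  qua <- pirt_fit("quadratic", 0.58, 28.7)
  expect_equal(predict_rsb(lin, 0.14), 1.44)
  expect_equal(predict_rsb(qua, 0.06), 0.68332)
  expect_equal(predict_rsb(lin, 0), 0.32)
  expect_equal(predict_rsb(qua, 0), 0.58)

  expect_equal(maintenance_fraction(lin, 0.06), 0.40)
  expect_equal(maintenance_fraction(qua, 0.06), 0.58 / 0.68332)
  expect_equal(maintenance_fraction(lin, 0), 1.0)
  expect_equal(maintenance_fraction(qua, 0), 1.0)

  # strictly decreasing in mu, tending to 0 for large mu
  grid <- seq(0, 1, by = 0.01)
  for (f in list(lin, qua)) {
    fr <- maintenance_fraction(f, grid)
    expect_true(all(diff(fr) < 0))
    expect_true(all(fr > 0 & fr <= 1))
    expect_lt(maintenance_fraction(f, 1e3), 1e-3)
  }
  expect_error(maintenance_fraction(pirt_fit("linear", -1, 0.1), 0.1),
               "non-positive")
})

test_that("data-frame interface, tidy and glance expose the fit consistently", {
  tx <- compute_rates(simulate_transect(n_samples = 22, seed = 47))
  # the linear form is misspecified for quadratic data and may warn about a
  # negative intercept; that is expected here
  fits <- suppressWarnings(fit_pirt(tx, form = "both", n_boot = 200, seed = 5))
  expect_named(fits, c("linear", "quadratic"))
  td <- tidy(fits$quadratic)
  expect_identical(td$term, c("rm", "b"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  gl <- glance(fits$quadratic)
  expect_identical(gl$form, "quadratic")
  expect_identical(gl$nobs, 22L)
  expect_gte(gl$r.squared, 0)
  expect_lte(gl$r.squared, 1)
  # the quadratic form fits its own generating process better than the line
  expect_gt(glance(fits$quadratic)$r.squared, 0.8)
})

test_that("fraction curves and fit plots are well-formed", {
  fit <- pirt_fit("quadratic", 0.58, 28.7)
  curve <- maintenance_curve(fit)
  expect_s3_class(curve, "fraction_curve")
  expect_true(all(diff(curve$fraction) < 0))
  p <- autoplot(curve)
  expect_s3_class(p, "ggplot")
  tx <- compute_rates(simulate_transect(n_samples = 10, seed = 48))
  f2 <- fit_pirt(tx, form = "quadratic", n_boot = 0)
  expect_s3_class(autoplot(f2), "ggplot")
})
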