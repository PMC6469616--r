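test_that("noiseless linear traces give the generating rate and the linear branch", {
  tr <- simulate_trace(duration_h = 24, linear_rate = 5, curvature = 0,
                       noise_sd = 0, seed = 1)
  res <- fit_trace(tr)
  expect_equal(res$rate, 5, tolerance = 1e-9)
  expect_identical(res$model_used, "linear")
})

test_that("noiseless curved traces take the quadratic branch and the 1-h derivative", {
  # O2(t) = 300 - 5 t - 12 t^2 (t in days): rate at 1 h is 5 + 24/24 = 6
  tr <- simulate_trace(duration_h = 24, linear_rate = 5, curvature = 24,
                       noise_sd = 0, seed = 1)
  res <- fit_trace(tr)
  expect_gt(res$r2_quadratic - res$r2_linear, 0.02)
  expect_identical(res$model_used, "quadratic")
  expect_equal(res$rate, 6, tolerance = 1e-9)

  # the derivative time is configurable: at 2 h the true rate is 5 + 24*2/24
  res2 <- fit_trace(tr, derivative_time_h = 2)
  expect_equal(res2$rate, 7, tolerance = 1e-9)
})

test_that("rate extraction is invariant to a constant oxygen offset", {
  tr <- simulate_trace(duration_h = 18, linear_rate = 4, curvature = 10,
                       noise_sd = 0.3, seed = 11)
  shifted <- tr
  shifted$o2 <- shifted$o2 + 50
  a <- fit_trace(tr)
  b <- fit_trace(shifted)
  expect_equal(a$rate, b$rate, tolerance = 1e-9)
  expect_identical(a$model_used, b$model_used)
  expect_equal(a$r2_linear, b$r2_linear, tolerance = 1e-9)
})

test_that("a batch of mixed traces matches a per-trace re-fit oracle", {
  set.seed(21)
  traces <- c(
    lapply(1:30, function(i) simulate_trace(duration_h = 24, linear_rate = 5,
                                            curvature = 0, noise_sd = 0.2,
                                            sample_id = paste0("L", i))),
    # decelerating consumption: the rate falls from 10 to 0 over the run, so
    # the 1-h rate exceeds the whole-trace average slope
    lapply(1:30, function(i) simulate_trace(duration_h = 24, linear_rate = 10,
                                            curvature = -10, noise_sd = 0.2,
                                            sample_id = paste0("Q", i))))
  batch <- fit_traces(traces)
  oracle <- vapply(traces, oracle_refit_trace, 0)
  expect_equal(batch$rate, oracle, tolerance = 1e-9)
  # curved traces are overwhelmingly classified nonlinear, straight ones not
  frac_nl <- mean(batch$model_used == "quadratic")
  expect_gt(mean(batch$model_used[31:60] == "quadratic"), 0.9)
  expect_lt(mean(batch$model_used[1:30] == "quadratic"), 0.2)
  # the linear model understates the 1-h rate on decelerating traces
  nl <- batch$model_used == "quadratic"
  lin_slopes <- vapply(traces[nl], function(tr) {
    t_day <- tr$time_h / 24
    -coef(lm(tr$o2 ~ t_day))[[2]]
  }, 0)
  expect_lt(mean(lin_slopes), mean(batch$rate[nl]))
})

test_that("the nonlinearity count is monotone in the threshold", {
  set.seed(31)
  traces <- lapply(1:40, function(i)
    simulate_trace(duration_h = 24, linear_rate = 5,
                   curvature = runif(1, 0, 30), noise_sd = 0.3))
  counts <- vapply(c(0, 0.005, 0.02, 0.05, 0.2), function(th)
    sum(fit_traces(traces, nonlinearity_threshold = th)$model_used == "quadratic"),
    0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("detection limit combines within-trace SE and between-control drift", {
  # perfectly flat noiseless controls: no drift, no SE -> limit 0
  flat <- lapply(1:3, function(i)
    simulate_trace(duration_h = 12, linear_rate = 0, noise_sd = 0, seed = i))
  expect_equal(detection_limit(flat), 0, tolerance = 1e-9)

  # rates +a and -a with zero within-trace SE: limit = sample SD = a*sqrt(2)
  a <- 0.4
  pair <- list(
    simulate_trace(duration_h = 12, linear_rate = a, noise_sd = 0, seed = 1),
    simulate_trace(duration_h = 12, linear_rate = -a, noise_sd = 0, seed = 1))
  expect_equal(detection_limit(pair), a * sqrt(2),
               tolerance = 1e-9)

  expect_error(detection_limit(flat[1]), "two control")
})

test_that("detection limit tracks the analytic slope-error expectation", {
  sigma <- 0.5
  ctl <- lapply(1:50, function(i)
    simulate_trace(duration_h = 12, linear_rate = 0, noise_sd = sigma,
                   seed = 100 + i))
  t_day <- ctl[[1]]$time_h / 24
  se_analytic <- sigma / sqrt(sum((t_day - mean(t_day))^2))
  # drift SD across controls is itself the slope sampling error, so the
  # expected limit is sqrt(SE^2 + SE^2)
  expect_equal(detection_limit(ctl), sqrt(2) * se_analytic, tolerance = 0.2)
})

test_that("below-detection flagging uses a strict inequality", {
  res <- tibble::tibble(rate = c(0.5, 0.9, 5))
  flagged <- flag_below_detection(res, 0.9)
  expect_identical(flagged$below_detection, c(TRUE, FALSE, FALSE))
  expect_identical(flagged$rate, res$rate)
})

test_that("trace validation rejects malformed input", {
  expect_error(fit_trace(tibble::tibble(time_h = 1:2, o2 = c(3, 2))), "3 points")
  bad <- tibble::tibble(time_h = c(0, 2, 1), o2 = c(3, 2, 1))
  expect_error(fit_trace(bad), "increasing")
})
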