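# Maintenance-model fitting. The simplified Pirt relation
#   R_sb = R_m + b * mu
# is fitted by model-II major-axis regression (both variables carry
# measurement error); an empirical quadratic alternative
#   R_sb = R_m + b * mu^2
# is fitted by least squares on mu^2. Uncertainty for both comes from a
# case-resampling percentile bootstrap ("trimmed range"); an analytic
# major-axis interval is available behind `interval_method`.

new_pirt_fit <- function(form, rm, b, r2 = NA_real_, rm_interval = c(NA_real_, NA_real_),
                         b_interval = c(NA_real_, NA_real_), n = NA_integer_,
                         interval_method = "none", data = NULL, seed = NULL,
                         n_boot = 0L) {
  structure(
    list(form = form, rm = rm, b = b, r2 = r2,
         rm_interval = rm_interval, b_interval = b_interval,
         n = n, interval_method = interval_method,
         data = data, seed = seed, n_boot = n_boot),
    class = "pirt_fit")
}

#' Construct a maintenance-model object from known coefficients
#'
#' Builds a fit object directly from coefficient values — e.g. published
#' estimates — so that downstream stages (prediction, maintenance-fraction
#' curves, annual integration) can run without refitting.
#'
#' @param form `"linear"` (R_sb = rm + b·µ) or `"quadratic"`
#'   (R_sb = rm + b·µ²).
#' @param rm Maintenance respiration intercept, fmol O2 day-1 cell-1.
#' @param b Slope coefficient (units depend on `form`).
#' @return A `pirt_fit` object.
#' @examples
#' fit <- pirt_fit("linear", rm = 0.32, b = 8.0)
#' maintenance_fraction(fit, 0.06)
#' @export
pirt_fit <- function(form = c("linear", "quadratic"), rm, b) {
  form <- match.arg(form)
  check_number(rm, "rm")
  check_number(b, "b")
  new_pirt_fit(form, rm, b, interval_method = "override")
}

ma_coefs <- function(x, y) {
  sxx <- var(x); syy <- var(y); sxy <- cov_(x, y)
  if (abs(sxy) < .Machine$double.eps * max(sxx, syy, 1)) {
    abort("Major-axis slope is undefined: the sample covariance is zero.")
  }
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  c(rm = mean(y) - slope * mean(x), b = slope)
}

cov_ <- function(x, y) mean((x - mean(x)) * (y - mean(y))) * length(x) / (length(x) - 1)

ols_mu2_coefs <- function(x, y) {
  x2 <- x^2
  sxx <- var(x2)
  if (sxx <= 0) abort("Quadratic fit is undefined: all growth rates are equal.")
  slope <- cov_(x2, y) / sxx
  c(rm = mean(y) - slope * mean(x2), b = slope)
}

# Percentile bootstrap over case resamples; coef_fun(x, y) -> c(rm, b).
# Degenerate resamples (zero covariance / variance) are redrawn implicitly by
# dropping them; with continuous data they have probability ~0.
boot_intervals <- function(x, y, coef_fun, n_boot, seed, level = 0.95) {
  n <- length(x)
  reps <- with_seed_if(seed, {
    purrr::map(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(coef_fun(x[idx], y[idx]), error = function(e) c(rm = NA_real_, b = NA_real_))
    })
  })
  m <- do.call(rbind, reps)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  list(rm = unname(quantile(m[, "rm"], probs, na.rm = TRUE)),
       b = unname(quantile(m[, "b"], probs, na.rm = TRUE)))
}

# Jolicoeur-style confidence interval for the major-axis slope: an interval
# on the axis angle from the covariance eigenvalues, mapped through tan();
# intercept limits follow through the centroid.
ma_analytic_intervals <- function(x, y, level = 0.95) {
  n <- length(x)
  sxx <- var(x); syy <- var(y); sxy <- cov_(x, y)
  S <- matrix(c(sxx, sxy, sxy, syy), 2)
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  l1 <- lam[1]; l2 <- lam[2]
  Fv <- qf(level, 1, n - 2)
  H <- 4 * l1 * l2 * Fv / ((n - 2) * (l1 - l2)^2)
  theta <- 0.5 * atan2(2 * sxy, sxx - syy)
  if (!is.finite(H) || H >= 1) {
    warn("Analytic major-axis interval is unbounded (axis poorly determined).")
    return(list(rm = c(-Inf, Inf), b = c(-Inf, Inf)))
  }
  phi <- atan(sqrt(H / (1 - H)))
  b_lim <- sort(tan(c(theta - phi, theta + phi)))
  rm_lim <- sort(mean(y) - b_lim * mean(x))
  list(rm = rm_lim, b = b_lim)
}

#' Fit the simplified linear Pirt model by major-axis regression
#'
#' Model-II regression minimising the total squared perpendicular distance of
#' the points to the line — appropriate because growth rate and respiration
#' are both measured with error. The maintenance respiration R_m is the
#' y-intercept at zero growth. R² is reported as the squared Pearson
#' correlation between the two variables.
#'
#' @param mu Specific growth rates, day-1 (length ≥ 3, non-constant).
#' @param r_sb Cell-specific respiration, fmol O2 day-1 cell-1.
#' @param interval_method `"bootstrap-percentile"` (case-resampling
#'   percentile interval, the default), `"major-axis-analytic"` (angle-based
#'   interval on the axis), or `"none"`.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap; required when
#'   `interval_method = "bootstrap-percentile"` so that intervals are
#'   reproducible.
#' @param level Confidence level (default 0.95).
#' @return A `pirt_fit` object with `form = "linear"`.
#' @examples
#' mu <- seq(0.02, 0.28, length.out = 12)
#' fit <- fit_major_axis(mu, 0.32 + 8 * mu, interval_method = "none")
#' coef(fit)
#' @export
fit_major_axis <- function(mu, r_sb,
                           interval_method = c("bootstrap-percentile",
                                               "major-axis-analytic", "none"),
                           n_boot = 2000, seed = NULL, level = 0.95) {
  interval_method <- match.arg(interval_method)
  check_xy(mu, r_sb)
  cf <- ma_coefs(mu, r_sb)
  if (interval_method == "bootstrap-percentile" && is.null(seed)) {
    abort("`seed` is required for the bootstrap interval.")
  }
  if (cf[["rm"]] < 0) {
    warn(sprintf("Fitted maintenance intercept is negative (%.3g); reported as-is.",
                 cf[["rm"]]))
  }
  ints <- switch(interval_method,
    "bootstrap-percentile" = boot_intervals(mu, r_sb, ma_coefs, n_boot, seed, level),
    "major-axis-analytic" = ma_analytic_intervals(mu, r_sb, level),
    "none" = list(rm = c(NA_real_, NA_real_), b = c(NA_real_, NA_real_)))
  new_pirt_fit("linear", cf[["rm"]], cf[["b"]],
               r2 = cor(mu, r_sb)^2,
               rm_interval = ints$rm, b_interval = ints$b,
               n = length(mu), interval_method = interval_method,
               data = tibble::tibble(mu = mu, r_sb = r_sb),
               seed = seed,
               n_boot = if (interval_method == "bootstrap-percentile") n_boot else 0L)
}

#' Fit the empirical quadratic maintenance model
#'
#' Least-squares fit of R_sb = R_m + b·µ², linear in µ² (mathematically
#' identical to a nonlinear fit of the quadratic form and numerically
#' stabler). Uncertainty is the 95% trimmed range: 2.5th–97.5th percentiles
#' of case-resampling bootstrap replicates.
#'
#' @inheritParams fit_major_axis
#' @param n_boot Bootstrap replicates (default 2000); 0 skips intervals.
#' @param seed Integer seed for the bootstrap; required when `n_boot > 0`.
#' @return A `pirt_fit` object with `form = "quadratic"`.
#' @examples
#' mu <- seq(0.02, 0.28, length.out = 12)
#' fit <- fit_quadratic(mu, 0.58 + 28.7 * mu^2, n_boot = 0)
#' coef(fit)
#' @export
fit_quadratic <- function(mu, r_sb, n_boot = 2000, seed = NULL, level = 0.95) {
  check_xy(mu, r_sb, need_cov = FALSE)
  if (var(mu) <= 0) abort("Growth rates are all equal; the fit is degenerate.")
  if (n_boot > 0 && is.null(seed)) {
    abort("`seed` is required for the bootstrap interval.")
  }
  cf <- ols_mu2_coefs(mu, r_sb)
  if (cf[["rm"]] < 0) {
    warn(sprintf("Fitted maintenance intercept is negative (%.3g); reported as-is.",
                 cf[["rm"]]))
  }
  yhat <- cf[["rm"]] + cf[["b"]] * mu^2
  r2 <- r_squared(r_sb, yhat)
  if (n_boot > 0) {
    ints <- boot_intervals(mu, r_sb, ols_mu2_coefs, n_boot, seed, level)
    method <- "bootstrap-percentile"
  } else {
    ints <- list(rm = c(NA_real_, NA_real_), b = c(NA_real_, NA_real_))
    method <- "none"
  }
  new_pirt_fit("quadratic", cf[["rm"]], cf[["b"]], r2 = r2,
               rm_interval = ints$rm, b_interval = ints$b,
               n = length(mu), interval_method = method,
               data = tibble::tibble(mu = mu, r_sb = r_sb),
               seed = seed, n_boot = as.integer(n_boot))
}

check_xy <- function(mu, r_sb, need_cov = TRUE) {
  if (length(mu) != length(r_sb)) abort("`mu` and `r_sb` must have equal length.")
  if (length(mu) < 3) abort("At least 3 samples are required.")
  if (any(!is.finite(mu)) || any(!is.finite(r_sb))) abort("Inputs must be finite.")
  if (need_cov && var(mu) <= 0) abort("Growth rates are all equal; the fit is degenerate.")
  invisible(NULL)
}

#' Fit the maintenance model to a rates table
#'
#' Data-frame-first wrapper around [fit_major_axis()] and [fit_quadratic()].
#'
#' @param data Data frame holding the rate columns (e.g. from
#'   [compute_rates()]).
#' @param form `"linear"`, `"quadratic"`, or `"both"`.
#' @param mu_col,rsb_col Column names (defaults `"mu"`, `"r_sb"`).
#' @param n_boot,seed,level Passed to the fitters.
#' @return A `pirt_fit`, or a named list of two fits for `form = "both"`.
#' @examples
#' tx <- compute_rates(simulate_transect(n_samples = 12, seed = 5))
#' fit_pirt(tx, form = "quadratic", n_boot = 200, seed = 1)
#' @export
fit_pirt <- function(data, form = c("linear", "quadratic", "both"),
                     mu_col = "mu", rsb_col = "r_sb",
                     n_boot = 2000, seed = NULL, level = 0.95) {
  form <- match.arg(form)
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!all(c(mu_col, rsb_col) %in% names(data))) {
    abort(sprintf("Columns `%s` and `%s` must be present.", mu_col, rsb_col))
  }
  mu <- data[[mu_col]]; r_sb <- data[[rsb_col]]
  lin <- function() fit_major_axis(mu, r_sb,
    interval_method = if (is.null(seed)) "none" else "bootstrap-percentile",
    n_boot = n_boot, seed = seed, level = level)
  qua <- function() fit_quadratic(mu, r_sb,
    n_boot = if (is.null(seed)) 0 else n_boot, seed = seed, level = level)
  switch(form,
    linear = lin(),
    quadratic = qua(),
    both = list(linear = lin(), quadratic = qua()))
}

#' Predict cell-specific respiration from a fitted maintenance model
#'
#' @param fit A `pirt_fit`.
#' @param mu Growth rates, day-1 (≥ 0).
#' @return Predicted R_sb, fmol O2 day-1 cell-1.
#' @export
predict_rsb <- function(fit, mu) {
  stopifnot(inherits(fit, "pirt_fit"))
  if (any(mu < 0)) abort("`mu` must be non-negative.")
  if (fit$form == "linear") fit$rm + fit$b * mu else fit$rm + fit$b * mu^2
}

#' @export
predict.pirt_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict_rsb(object, object$data$mu))
  mu <- if (is.data.frame(newdata)) newdata$mu else newdata
  predict_rsb(object, mu)
}

#' Maintenance fraction of cell-specific respiration
#'
#' The share of respiration that funds maintenance,
#' \eqn{R_m / R_{sb}(\mu)}; 1 at zero growth, decreasing in µ.
#'
#' @param fit A `pirt_fit`.
#' @param mu Growth rates, day-1 (≥ 0).
#' @return Fractions in (0, 1\] (for positive coefficients).
#' @examples
#' maintenance_fraction(pirt_fit("linear", 0.32, 8.0), 0.06)   # 0.40
#' @export
maintenance_fraction <- function(fit, mu) {
  pred <- predict_rsb(fit, mu)
  if (any(pred <= 0)) {
    abort("Predicted respiration is non-positive; the fraction is undefined.")
  }
  fit$rm / pred
}

#' Maintenance-fraction curve over a growth-rate grid
#'
#' @param fit A `pirt_fit`.
#' @param mu_grid Growth rates, day-1; default a fine grid over 0–0.28.
#' @return A tibble (`mu`, `fraction`, `form`) of class `fraction_curve`.
#' @export
maintenance_curve <- function(fit, mu_grid = seq(0.001, 0.28, by = 0.001)) {
  out <- tibble::tibble(mu = mu_grid,
                        fraction = maintenance_fraction(fit, mu_grid),
                        form = fit$form)
  class(out) <- c("fraction_curve", class(out))
  out
}

# broom-style accessors ---------------------------------------------------

#' @export
coef.pirt_fit <- function(object, ...) c(rm = object$rm, b = object$b)

#' Tidy a maintenance-model fit
#'
#' @param x A `pirt_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.pirt_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rm", "b"),
    estimate = c(x$rm, x$b),
    conf.low = c(x$rm_interval[1], x$b_interval[1]),
    conf.high = c(x$rm_interval[2], x$b_interval[2]))
}

#' One-row model summary of a maintenance-model fit
#'
#' @param x A `pirt_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `form`, `r.squared`, `nobs`,
#'   `interval.method`, `n.boot`.
#' @export
glance.pirt_fit <- function(x, ...) {
  tibble::tibble(form = x$form, r.squared = x$r2, nobs = x$n,
                 interval.method = x$interval_method, n.boot = x$n_boot)
}

#' @export
print.pirt_fit <- function(x, ...) {
  cat(sprintf("Maintenance model (%s form), n = %s\n", x$form,
              ifelse(is.na(x$n), "-", x$n)))
  cat(sprintf("  R_m = %.4g fmol O2 d-1 cell-1", x$rm))
  if (!is.na(x$rm_interval[1])) {
    cat(sprintf("  [%.4g, %.4g]", x$rm_interval[1], x$rm_interval[2]))
  }
  cat(sprintf("\n  b   = %.4g", x$b))
  if (!is.na(x$b_interval[1])) {
    cat(sprintf("  [%.4g, %.4g]", x$b_interval[1], x$b_interval[2]))
  }
  if (!is.na(x$r2)) cat(sprintf("\n  R^2 = %.3f", x$r2))
  cat(sprintf("\n  intervals: %s\n", x$interval_method))
  invisible(x)
}
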