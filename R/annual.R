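# Histogram-weighted annual integration of the maintenance contribution:
#   R_mA / R_sbA = sum_h f_h * R_m(mu_h) / R_sb(mu_h)
# where f_h are the fractions of annual growth-rate observations in uniform
# bins (default width 0.02 day-1 over 0.02-0.28 day-1) and the per-bin ratio
# is evaluated at the bin midpoint.

#' Bin annual growth-rate observations into a histogram
#'
#' Values are assigned to half-open bins \[lo, hi) of uniform width (the last
#' bin is closed above). Observations outside `range` are clamped into the
#' first or last bin rather than dropped; the clamped counts are kept in the
#' attributes so a faithful input (no out-of-range values) is verifiable.
#'
#' @param mu_values Growth rates, day-1 (non-empty).
#' @param bin_width Bin width, day-1 (default 0.02).
#' @param range Histogram range, day-1 (default c(0.02, 0.28)); must be an
#'   integer number of bins wide.
#' @return A tibble of class `mu_distribution` with columns `bin_lo`,
#'   `bin_hi`, `midpoint`, `count`, `f_h` (fractions summing to 1);
#'   attributes `n_total`, `n_below`, `n_above`, `bin_width`.
#' @examples
#' d <- bin_mu(simulate_annual_mu(500, seed = 1))
#' sum(d$f_h)
#' @export
bin_mu <- function(mu_values, bin_width = 0.02, range = c(0.02, 0.28)) {
  if (length(mu_values) == 0) abort("`mu_values` must be non-empty.")
  if (any(!is.finite(mu_values))) abort("`mu_values` must be finite.")
  check_number(bin_width, "bin_width", lower = 0, allow_zero = FALSE)
  check_range(range, "range")
  n_bins <- (range[2] - range[1]) / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-8) {
    abort("`range` must span a whole number of bins.")
  }
  n_bins <- as.integer(round(n_bins))
  edges <- range[1] + bin_width * (0:n_bins)
  n_below <- sum(mu_values < range[1])
  n_above <- sum(mu_values > range[2])
  clamped <- pmin(pmax(mu_values, range[1]), range[2])
  # half-open [lo, hi); top edge folds into the last bin
  idx <- pmin(floor((clamped - range[1]) / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  out <- tibble::tibble(
    bin_lo = edges[-(n_bins + 1L)],
    bin_hi = edges[-1L],
    midpoint = (edges[-(n_bins + 1L)] + edges[-1L]) / 2,
    count = counts,
    f_h = counts / length(mu_values))
  attr(out, "n_total") <- length(mu_values)
  attr(out, "n_below") <- n_below
  attr(out, "n_above") <- n_above
  attr(out, "bin_width") <- bin_width
  class(out) <- c("mu_distribution", class(out))
  out
}

#' Annual maintenance contribution from a growth-rate histogram
#'
#' Weighted sum of the maintenance fraction over the histogram bins,
#' evaluating R_m/R_sb at each bin midpoint and weighting by the bin
#' fraction f_h. With positive coefficients the result lies in (0, 1\].
#'
#' @param dist A `mu_distribution` from [bin_mu()].
#' @param fit A `pirt_fit`.
#' @return A list of class `annual_result`: `ratio` (R_mA/R_sbA), `form`,
#'   and `per_bin` (tibble with `midpoint`, `f_h`, `fraction`,
#'   `contribution`).
#' @examples
#' d <- bin_mu(simulate_annual_mu(500, seed = 1))
#' annual_contribution(d, pirt_fit("linear", 0.32, 8.0))$ratio
#' @export
annual_contribution <- function(dist, fit) {
  if (!inherits(dist, "mu_distribution")) abort("`dist` must come from bin_mu().")
  stopifnot(inherits(fit, "pirt_fit"))
  if (abs(sum(dist$f_h) - 1) > 1e-12) abort("Bin fractions must sum to 1.")
  pred <- predict_rsb(fit, dist$midpoint)
  if (any(pred <= 0)) {
    abort("Predicted respiration is non-positive in at least one bin.")
  }
  frac <- fit$rm / pred
  per_bin <- tibble::tibble(midpoint = dist$midpoint, f_h = dist$f_h,
                            fraction = frac, contribution = dist$f_h * frac)
  structure(list(ratio = sum(per_bin$contribution), form = fit$form,
                 per_bin = per_bin),
            class = "annual_result")
}

#' @export
print.annual_result <- function(x, ...) {
  cat(sprintf("Annual maintenance contribution (%s form): %.1f%%\n",
              x$form, 100 * x$ratio))
  invisible(x)
}

#' Tidy the per-bin breakdown of an annual contribution
#'
#' @param x An `annual_result`.
#' @param ... Unused.
#' @return The per-bin tibble (`midpoint`, `f_h`, `fraction`, `contribution`).
#' @export
tidy.annual_result <- function(x, ...) x$per_bin

#' One-row summary of an annual contribution
#'
#' @param x An `annual_result`.
#' @param ... Unused.
#' @return A one-row tibble: `ratio`, `form`, `n.bins`.
#' @export
glance.annual_result <- function(x, ...) {
  tibble::tibble(ratio = x$ratio, form = x$form, n.bins = nrow(x$per_bin))
}
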