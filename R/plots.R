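# Diagnostic figures: fit scatter with model curves, maintenance-fraction
# curves, and the annual growth-rate histogram.

#' Plot a maintenance-model fit
#'
#' Scatter of cell-specific respiration against growth rate with the fitted
#' model curve.
#'
#' @param object A `pirt_fit` carrying its data.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pirt_fit <- function(object, ...) {
  if (is.null(object$data)) {
    abort("This fit carries no data to plot (coefficients-only object).")
  }
  grid <- tibble::tibble(mu = seq(0, max(object$data$mu), length.out = 200))
  grid$r_sb <- predict_rsb(object, grid$mu)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mu, y = .data$r_sb)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(
      x = expression(mu ~ (day^-1)),
      y = expression(R[sb] ~ (fmol ~ O[2] ~ day^-1 ~ cell^-1)),
      title = sprintf("Maintenance model (%s form)", object$form)) +
    ggplot2::theme_minimal()
}

#' Plot a maintenance-fraction curve
#'
#' @param object A `fraction_curve` from [maintenance_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fraction_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mu, y = .data$fraction)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = expression(mu ~ (day^-1)),
                  y = expression(R[m] / R[sb]),
                  title = sprintf("Maintenance fraction (%s form)",
                                  object$form[1])) +
    ggplot2::theme_minimal()
}

#' Plot an annual growth-rate histogram
#'
#' @param object A `mu_distribution` from [bin_mu()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mu_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$midpoint, y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width") * 0.92,
                      fill = "grey40") +
    ggplot2::labs(x = expression(mu ~ (day^-1)), y = "observations",
                  title = "Annual growth-rate distribution") +
    ggplot2::theme_minimal()
}
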