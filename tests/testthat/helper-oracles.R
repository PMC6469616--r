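# Independent oracles used across the suite. Each deliberately avoids the
# implementation path it checks.

# Major-axis line by brute force: for a fixed direction angle the optimal
# offset runs the line through the centroid (plain least-squares profiling);
# the angle is then found by grid search plus Newton refinement on the
# perpendicular sum of squares.
oracle_major_axis <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  g <- function(th) sum((sin(th) * xc - cos(th) * yc)^2)
  grid <- seq(-pi / 2, pi / 2, length.out = 2001)
  th <- grid[which.min(vapply(grid, g, 0))]
  for (k in 1:50) {
    s <- sin(th); cth <- cos(th)
    u <- s * xc - cth * yc
    v <- cth * xc + s * yc
    g1 <- 2 * sum(u * v)
    g2 <- 2 * sum(v^2 - u^2)
    step <- g1 / g2
    if (!is.finite(step)) break
    th <- th - step
    if (abs(step) < 1e-15) break
  }
  b <- tan(th)
  c(rm = mean(y) - b * mean(x), b = b)
}

# Kendall tau-b by explicit pair counting with tie correction.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# Per-observation mean of the maintenance fraction (the bin-free limit of
# the histogram-weighted annual ratio).
oracle_mean_fraction <- function(mu, fit) {
  mean(fit$rm / pirtfield::predict_rsb(fit, mu))
}

# Straight-line / parabola refits used as re-fit oracles for trace batches.
oracle_refit_trace <- function(trace, threshold = 0.02, deriv_h = 1) {
  t_day <- (trace$time_h - trace$time_h[1]) / 24
  o2 <- trace$o2
  lin <- lm(o2 ~ t_day)
  qua <- lm(o2 ~ poly(t_day, 2, raw = TRUE))
  r2 <- function(m) 1 - sum(residuals(m)^2) / sum((o2 - mean(o2))^2)
  if (r2(qua) - r2(lin) >= threshold) {
    cf <- coef(qua)
    -(cf[[2]] + 2 * cf[[3]] * deriv_h / 24)
  } else {
    -coef(lin)[[2]]
  }
}
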