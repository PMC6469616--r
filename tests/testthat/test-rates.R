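test_that("thymidine conversion applies the seasonal TCF", {
  spring <- conversion_config(tcf = 1.2e18)
  summer <- conversion_config(tcf = 1.7e18)
  expect_equal(cells_from_thymidine(1e-18, spring), 1.2)
  expect_equal(cells_from_thymidine(2e-18, summer), 3.4)
  expect_equal(cells_from_thymidine(0, summer), 0)
  expect_error(cells_from_thymidine(-1e-18, summer), "non-negative")
})

test_that("specific rates are the stated ratios with the right units", {
  expect_equal(specific_growth_rate(3.2e7, 1e9), 0.032)
  expect_equal(specific_growth_rate(0, 1e9), 0)
  expect_error(specific_growth_rate(1, 0), "positive")

  # umol dm-3 d-1 over cells dm-3, reported in fmol cell-1 d-1
  expect_equal(specific_respiration(1.44, 1e9), 1.44)
  expect_equal(specific_respiration(0, 1e9), 0)
  expect_error(specific_respiration(1, 0), "positive")

  # vectorised division matches row-wise brute force
  set.seed(9)
  prod <- runif(20, 1e6, 1e8); ab <- runif(20, 1e9, 5e9)
  expect_equal(specific_growth_rate(prod, ab),
               vapply(seq_along(prod), function(i) prod[i] / ab[i], 0))
})

test_that("cell carbon follows the allometric form", {
  cfg <- conversion_config()
  expect_equal(cell_carbon(1, cfg), cfg$carbon_alpha)
  lin <- conversion_config(carbon_alpha = 120, carbon_beta = 1)
  expect_equal(cell_carbon(0.5, lin), 60)
  # default allometry at a typical estuarine cell volume lands on the same
  # order of magnitude as a 1.5 fmol C cell-1 (= 18 fg) direct calibration
  fg <- cell_carbon(0.0833, cfg)
  expect_gt(fg / 18, 0.5)
  expect_lt(fg / 18, 2)
  expect_error(cell_carbon(0, cfg), "positive")
})

test_that("growth efficiency is P/(P + RQ R) with correct limits", {
  cfg <- conversion_config(rq = 0.9)
  expect_equal(bge(1, 10, cfg), 0.10)
  expect_equal(bge(0, 5, cfg), 0)
  expect_equal(bge(5, 0, cfg), 1)
  expect_error(bge(0, 0, cfg), "undefined")
  # monotone: increasing in production, decreasing in respiration
  p <- seq(0.1, 2, length.out = 10)
  expect_true(all(diff(bge(p, 5, cfg)) > 0))
  r <- seq(0.1, 2, length.out = 10)
  expect_true(all(diff(bge(1, r, cfg)) < 0))
})

test_that("carbon-specific maintenance reproduces the O2-to-carbon arithmetic", {
  expect_equal(round(carbon_specific_maintenance(0.58, 1.5, rq = 1), 2), 0.39)
  expect_equal(carbon_specific_maintenance(1.5, 1.5, rq = 1), 1)
})

test_that("compute_rates round-trips the synthetic generator exactly", {
  tx <- simulate_transect(n_samples = 15, seed = 12)
  r <- compute_rates(tx)
  expect_equal(r$r_sb, tx$true_r_sb, tolerance = 1e-12)
  expect_equal(r$mu, tx$true_mu, tolerance = 1e-12)
  expect_true(all(r$bge >= 0 & r$bge <= 1))
  # homogeneity: scaling abundance and bulk quantities together leaves the
  # specific rates and BGE unchanged
  sc <- tx
  sc$abundance <- sc$abundance * 3
  sc$r_bulk <- sc$r_bulk * 3
  sc$cell_production <- sc$cell_production * 3
  sc$thymidine_uptake <- sc$thymidine_uptake * 3
  r2 <- compute_rates(sc)
  expect_equal(r2$mu, r$mu, tolerance = 1e-12)
  expect_equal(r2$r_sb, r$r_sb, tolerance = 1e-12)
  expect_equal(r2$bge, r$bge, tolerance = 1e-12)
})

test_that("compute_rates accepts thymidine uptake in place of cell production", {
  tx <- simulate_transect(n_samples = 8, seed = 13, tcf = 1.7e18)
  tx$cell_production <- NULL
  r <- compute_rates(tx, conversion_config(tcf = 1.7e18))
  expect_equal(r$mu, tx$true_mu, tolerance = 1e-9)
  tx$thymidine_uptake <- NULL
  expect_error(compute_rates(tx), "thymidine_uptake")
})

test_that("conversion settings are validated", {
  expect_error(conversion_config(tcf = 0), "tcf")
  expect_error(conversion_config(rq = 2.5), "rq")
  expect_error(conversion_config(rq = 0), "rq")
})
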