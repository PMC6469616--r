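# pirtfield

Estimation of bacterial maintenance respiration from field respirometry and
growth-rate data.

Heterotrophic bacterioplankton spend part of their respiration on functions
other than growth — membrane potential, turnover, motility. The classic
chemostat description of this is the Pirt model, which, simplified for field
data where the specific growth rate µ approaches zero, reads

```
R_sb = R_m + b · µ
```

where `R_sb` is cell-specific respiration (fmol O₂ day⁻¹ cell⁻¹), `µ` the
cell-specific growth rate (day⁻¹), `R_m` the maintenance respiration (the
intercept at zero growth), and `b` a composite growth-cost coefficient.
Because both `µ` and `R_sb` carry measurement error, `R_m` is estimated by
model-II **major-axis regression** (minimising perpendicular distances). An
empirical **quadratic** alternative,

```
R_sb = R_m + b_n · µ²
```

often describes field data better at low growth; it is fitted by least
squares on µ², with 95% *trimmed-range* uncertainty (percentile intervals
from a case-resampling bootstrap). From a fitted model, the maintenance
share of respiration is `R_m / R_sb(µ)`, and its annual-scale contribution
is a histogram-weighted sum over a year of in-situ growth-rate
observations:

```
R_mA / R_sbA = Σ_h f_h · R_m(µ_h) / R_sb(µ_h)
```

with `f_h` the fraction of observations in growth-rate bins of 0.02 day⁻¹.

The package covers the full path from raw data to that annual number, for
aquatic microbial ecologists working with optode respirometry and
thymidine-incorporation production data:

* **Respirometry** — extract respiration rates from minute-resolution
  dissolved-oxygen traces: linear fit for monotonic declines, first
  derivative of a second-order polynomial at 1 h for nonlinear ones
  (decided by a ΔR² ≥ 0.02 rule), plus a control-based detection limit.
* **Rates** — thymidine → cell production (seasonal conversion factor),
  cell volume → cell carbon (allometric), µ, cell-specific respiration,
  and bacterial growth efficiency `BGE = P_b / (P_b + RQ·R_b)`.
* **Maintenance model** — `fit_pirt()` / `fit_major_axis()` /
  `fit_quadratic()`, with `tidy()`, `glance()`, `autoplot()`,
  `maintenance_fraction()` and `maintenance_curve()`.
* **Annual integration** — `bin_mu()` and `annual_contribution()`.
* **Covariate screening** — tie-corrected Kendall τ_b against temperature,
  nutrient pools and stoichiometric ratios, Bonferroni-controlled.
* **Synthetic data** — `simulate_trace()`, `simulate_transect()`,
  `simulate_annual_mu()` generate all three input kinds with known ground
  truth, so every stage is testable end to end without field data.
* **Pipeline** — `run_pipeline()` / `run_demo()` execute
  traces → rates → fit → annual → screen with a reproducible manifest.

## Worked example

```r
library(pirtfield)

# a productive-season transect with known truth (rm = 0.58, b = 28.7)
tx    <- simulate_transect(n_samples = 22, form = "quadratic", seed = 3)
rates <- compute_rates(tx)
fit   <- fit_pirt(rates, form = "quadratic", n_boot = 500, seed = 9)
fit
#> Maintenance model (quadratic form), n = 22
#>   R_m = 0.5997 fmol O2 d-1 cell-1  [0.552, 0.6423]
#>   b   = 27.48  [26.02, 28.92]
#>   R^2 = 0.987
#>   intervals: bootstrap-percentile
```

The fitted maintenance respiration (≈0.60 fmol O₂ day⁻¹ cell⁻¹, trimmed
range in brackets) recovers the generating value 0.58. Downstream:

```r
maintenance_fraction(fit, 0.06)      # share of respiration at mu = 0.06/d
#> [1] 0.8583946
mu_year <- simulate_annual_mu(2000, seed = 2)   # skewed annual mu set
annual_contribution(bin_mu(mu_year), fit)
#> Annual maintenance contribution (quadratic form): 71.6%
```

So at a growth rate of 0.06 day⁻¹ about 86% of cell-specific respiration
funds maintenance under this fit, and weighting over the simulated annual
growth-rate distribution puts the maintenance share of annual respiration
near 72%. With published coefficient sets you can skip fitting entirely:

```r
maintenance_fraction(pirt_fit("linear", rm = 0.32, b = 8.0), 0.06)
#> [1] 0.4
maintenance_fraction(pirt_fit("quadratic", rm = 0.58, b = 28.7), 0.06)
#> [1] 0.848797
```

## Layout

| Path | Contents |
| --- | --- |
| `R/synthetic-data.R` | generators with ground truth |
| `R/respirometry.R` | trace fitting, detection limit |
| `R/rates.R` | conversions, µ, R_sb, BGE |
| `R/pirt.R` | major-axis + quadratic fits, fractions |
| `R/annual.R` | histogram weighting |
| `R/correlations.R` | Kendall screening |
| `R/pipeline.R` | end-to-end orchestration |
| `vignettes/maintenance-respiration.Rmd` | methods notes |
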