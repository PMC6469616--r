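# Conversion of raw field measurements into the model's quantities:
# cell production from thymidine uptake, cell carbon from cell volume,
# specific growth and respiration rates, and bacterial growth efficiency.

#' Conversion settings for rate calculations
#'
#' Bundles the empirical conversion factors used throughout the rate
#' calculations.
#'
#' @param tcf Thymidine conversion factor, cells per mol thymidine
#'   incorporated. Season-specific; typical estuarine determinations are
#'   1.2 × 10^18 (spring) to 1.7 × 10^18 (late summer). Default is the
#'   productive-season value.
#' @param rq Respiratory quotient, mol CO2 produced per mol O2 consumed
#'   (default 0.9). Must lie in (0, 2].
#' @param carbon_alpha,carbon_beta Allometric cell-carbon parameters:
#'   carbon per cell (fg C) = `carbon_alpha` × volume^`carbon_beta` with
#'   volume in µm³. Defaults 120 and 0.72 are a widely used allometric
#'   parameterisation for aquatic bacteria; override to match a local
#'   calibration.
#' @return A list of class `conversion_config`.
#' @examples
#' conversion_config(tcf = 1.2e18)
#' @export
conversion_config <- function(tcf = 1.7e18, rq = 0.9,
                              carbon_alpha = 120, carbon_beta = 0.72) {
  check_number(tcf, "tcf", lower = 0, allow_zero = FALSE)
  check_number(rq, "rq", lower = 0, upper = 2, allow_zero = FALSE)
  check_number(carbon_alpha, "carbon_alpha", lower = 0, allow_zero = FALSE)
  check_number(carbon_beta, "carbon_beta")
  structure(list(tcf = tcf, rq = rq, carbon_alpha = carbon_alpha,
                 carbon_beta = carbon_beta),
            class = "conversion_config")
}

#' @export
print.conversion_config <- function(x, ...) {
  cat("Conversion settings:\n")
  cat(sprintf("  TCF: %.3g cells (mol thymidine)^-1\n", x$tcf))
  cat(sprintf("  RQ: %.2f mol CO2 (mol O2)^-1\n", x$rq))
  cat(sprintf("  Cell carbon: %.3g fg C x V^%.2f (V in um^3)\n",
              x$carbon_alpha, x$carbon_beta))
  invisible(x)
}

#' Cell production from thymidine incorporation
#'
#' @param uptake Thymidine incorporation, mol thymidine dm-3 day-1 (≥ 0).
#' @param config A [conversion_config()].
#' @return Cell production, cells dm-3 day-1 (`uptake` × TCF).
#' @examples
#' cells_from_thymidine(1e-18, conversion_config(tcf = 1.2e18))
#' @export
cells_from_thymidine <- function(uptake, config = conversion_config()) {
  stopifnot(inherits(config, "conversion_config"))
  if (any(!is.finite(uptake)) || any(uptake < 0)) {
    abort("`uptake` must be non-negative and finite.")
  }
  uptake * config$tcf
}

#' Specific growth rate from production and abundance
#'
#' @param cell_production Cells dm-3 day-1.
#' @param abundance Cells dm-3 (> 0).
#' @return Specific growth rate µ, day-1.
#' @export
specific_growth_rate <- function(cell_production, abundance) {
  if (any(!is.finite(abundance)) || any(abundance <= 0)) {
    abort("`abundance` must be positive.")
  }
  cell_production / abundance
}

#' Cell-specific respiration from bulk respiration and abundance
#'
#' @param r_bulk Bulk community respiration, µmol O2 dm-3 day-1.
#' @param abundance Cells dm-3 (> 0).
#' @return Cell-specific respiration, fmol O2 day-1 cell-1
#'   (µmol → fmol carries a factor 10^9).
#' @export
specific_respiration <- function(r_bulk, abundance) {
  if (any(!is.finite(abundance)) || any(abundance <= 0)) {
    abort("`abundance` must be positive.")
  }
  r_bulk / abundance * 1e9
}

#' Cell carbon content from mean cell volume
#'
#' Allometric conversion carbon = alpha × V^beta, fg C per cell.
#'
#' @param mean_cell_volume Mean cell volume, µm³ (> 0).
#' @param config A [conversion_config()].
#' @return Cell carbon, fg C cell-1.
#' @export
cell_carbon <- function(mean_cell_volume, config = conversion_config()) {
  stopifnot(inherits(config, "conversion_config"))
  if (any(!is.finite(mean_cell_volume)) || any(mean_cell_volume <= 0)) {
    abort("`mean_cell_volume` must be positive.")
  }
  config$carbon_alpha * mean_cell_volume^config$carbon_beta
}

#' Bacterial growth efficiency
#'
#' \deqn{\mathrm{BGE} = \frac{P_b}{P_b + \mathrm{RQ} \cdot R_b},}
#' where \eqn{P_b} is biomass production in carbon units and \eqn{R_b} the
#' community respiration as O2 consumption, converted to carbon with the
#' respiratory quotient.
#'
#' @param p_b_carbon Biomass production, µmol C dm-3 day-1 (≥ 0).
#' @param r_b_o2 Community respiration, µmol O2 dm-3 day-1 (≥ 0). Must not be
#'   zero together with `p_b_carbon`.
#' @param config A [conversion_config()] supplying RQ.
#' @return Growth efficiency in \[0, 1\].
#' @examples
#' bge(1, 10, conversion_config(rq = 0.9))   # 0.10
#' @export
bge <- function(p_b_carbon, r_b_o2, config = conversion_config()) {
  stopifnot(inherits(config, "conversion_config"))
  if (any(p_b_carbon < 0) || any(r_b_o2 < 0)) {
    abort("Production and respiration must be non-negative.")
  }
  if (any(p_b_carbon == 0 & r_b_o2 == 0)) {
    abort("BGE is undefined when production and respiration are both zero.")
  }
  p_b_carbon / (p_b_carbon + config$rq * r_b_o2)
}

#' Carbon-specific maintenance rate
#'
#' Expresses a cell-specific maintenance respiration as a carbon-specific
#' rate: O2 consumption is converted to carbon with the respiratory quotient
#' and divided by the cell carbon content,
#' \deqn{r = R_m \cdot \mathrm{RQ} / C_{cell} \quad [\mathrm{day}^{-1}].}
#'
#' @param rm Maintenance respiration, fmol O2 day-1 cell-1.
#' @param cell_carbon_fmol Cell carbon content, fmol C cell-1.
#' @param rq Respiratory quotient (default 1 for a direct O2:C equivalence).
#' @return Carbon-specific maintenance metabolism, day-1.
#' @examples
#' carbon_specific_maintenance(0.58, 1.5)   # ~0.39 day-1
#' @export
carbon_specific_maintenance <- function(rm, cell_carbon_fmol, rq = 1) {
  check_number(cell_carbon_fmol, "cell_carbon_fmol", lower = 0, allow_zero = FALSE)
  check_number(rq, "rq", lower = 0, upper = 2, allow_zero = FALSE)
  rm * rq / cell_carbon_fmol
}

# fg C cell-1 x cells dm-3 d-1 -> umol C dm-3 d-1 (12 g mol-1)
FG_PER_UMOL_C <- 12 * 1e9

#' Derive model quantities for a transect table
#'
#' Takes a transect table (one row per station × depth sample) and computes
#' the quantities the maintenance model is fitted to: specific growth rate
#' `mu` (day-1), cell-specific respiration `r_sb` (fmol O2 day-1 cell-1),
#' production and respiration in carbon units, and growth efficiency `bge`.
#'
#' Exactly one of `thymidine_uptake` (mol thymidine dm-3 day-1) or
#' `cell_production` (cells dm-3 day-1) must be present per row; uptake is
#' converted with the TCF. A pre-computed `mu` column, when present, is kept
#' as-is and the production-based calculation is skipped.
#'
#' @param records Data frame with columns `abundance`, `r_bulk`,
#'   `mean_cell_volume`, and `thymidine_uptake` and/or `cell_production`.
#'   Extra columns pass through.
#' @param config A [conversion_config()].
#' @return The input tibble augmented with `mu`, `r_sb`, `cell_carbon_fg`,
#'   `p_b_carbon`, `r_b_carbon` and `bge`.
#' @examples
#' tx <- simulate_transect(n_samples = 6, seed = 2)
#' compute_rates(tx)[, c("mu", "r_sb", "bge")]
#' @export
compute_rates <- function(records, config = conversion_config()) {
  stopifnot(inherits(config, "conversion_config"))
  if (!is.data.frame(records)) abort("`records` must be a data frame.")
  needed <- c("abundance", "r_bulk", "mean_cell_volume")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  has_uptake <- "thymidine_uptake" %in% names(records)
  has_prod <- "cell_production" %in% names(records)
  if (!has_uptake && !has_prod) {
    abort("Provide `thymidine_uptake` or `cell_production`.")
  }
  if (any(records$abundance <= 0)) abort("`abundance` must be positive.")
  if (any(records$r_bulk < 0)) abort("`r_bulk` must be non-negative.")
  out <- tibble::as_tibble(records)
  if (!has_prod) {
    out <- dplyr::mutate(out,
      cell_production = cells_from_thymidine(.data$thymidine_uptake, config))
  }
  out <- dplyr::mutate(out,
    cell_carbon_fg = cell_carbon(.data$mean_cell_volume, config),
    p_b_carbon = .data$cell_production * .data$cell_carbon_fg / FG_PER_UMOL_C,
    r_b_carbon = config$rq * .data$r_bulk,
    r_sb = specific_respiration(.data$r_bulk, .data$abundance))
  if (!"mu" %in% names(out)) {
    out <- dplyr::mutate(out,
      mu = specific_growth_rate(.data$cell_production, .data$abundance))
  }
  dplyr::mutate(out,
    bge = ifelse(.data$p_b_carbon == 0 & .data$r_bulk == 0, NA_real_,
                 .data$p_b_carbon / (.data$p_b_carbon + config$rq * .data$r_bulk)))
}
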