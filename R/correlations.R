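# Nonparametric covariate screening: tie-corrected Kendall correlations of
# cell-specific respiration against environmental factors, with Bonferroni
# control within a declared family of tests.

#' Kendall's tau-b with a two-sided test
#'
#' Tie-corrected Kendall rank correlation. The two-sided p-value comes from
#' `stats::cor.test`: exact for small samples without ties, otherwise the
#' normal approximation with tie correction.
#'
#' @param x,y Numeric vectors of equal length ≥ 3; neither may be constant.
#' @return A one-row tibble: `tau_b`, `p_raw`, `n`.
#' @examples
#' kendall_tau_b(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("At least 3 complete pairs are required.")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("Kendall's tau is undefined when a variable is completely tied.")
  }
  tau <- cor(x, y, method = "kendall")
  p <- suppressWarnings(
    cor.test(x, y, method = "kendall", alternative = "two.sided")$p.value)
  tibble::tibble(tau_b = tau, p_raw = p, n = length(x))
}

#' Screen covariates against cell-specific respiration
#'
#' Computes Kendall's tau-b between a response (by default `r_sb`) and each
#' factor, within each subset defined by the grouping columns, and applies a
#' Bonferroni correction. The multiple-testing family defaults to the
#' factors within one subset (so with 7 factors each raw p is multiplied
#' by 7); `family = "global"` uses all factor-by-subset tests instead. The
#' molar stoichiometric ratios `cp` (DOC/TDP) and `cn` (DOC/TDN) are derived
#' on the fly when requested and absent.
#'
#' @param data Data frame holding the response, factors and grouping
#'   columns (typically a [compute_rates()] output joined with sample
#'   metadata).
#' @param factors Character vector of factor columns to screen (default the
#'   standard set: temperature, tdp, tdn, doc, cp, cn, mu).
#' @param response Response column (default `"r_sb"`).
#' @param group_vars Optional character vector of grouping columns (e.g.
#'   `c("month", "depth_layer")`); `NULL` screens the whole table as one
#'   subset.
#' @param alpha Significance level applied to adjusted p-values
#'   (default 0.05).
#' @param family `"within-subset"` (default) or `"global"` Bonferroni
#'   family.
#' @return A tibble with one row per factor × subset: grouping columns,
#'   `factor`, `tau_b`, `p_raw`, `p_adjusted`, `n`, `significant`.
#' @examples
#' tx <- compute_rates(simulate_transect(n_samples = 16, seed = 4))
#' screen_correlations(tx, factors = c("temperature", "tdp", "mu"))
#' @export
screen_correlations <- function(data,
                                factors = c("temperature", "tdp", "tdn",
                                            "doc", "cp", "cn", "mu"),
                                response = "r_sb", group_vars = NULL,
                                alpha = 0.05,
                                family = c("within-subset", "global")) {
  family <- match.arg(family)
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!response %in% names(data)) {
    abort(sprintf("Response column `%s` is missing.", response))
  }
  data <- tibble::as_tibble(data)
  if ("cp" %in% factors && !"cp" %in% names(data)) {
    if (!all(c("doc", "tdp") %in% names(data))) {
      abort("Columns `doc` and `tdp` are needed to derive `cp`.")
    }
    data$cp <- data$doc / data$tdp
  }
  if ("cn" %in% factors && !"cn" %in% names(data)) {
    if (!all(c("doc", "tdn") %in% names(data))) {
      abort("Columns `doc` and `tdn` are needed to derive `cn`.")
    }
    data$cn <- data$doc / data$tdn
  }
  missing_cols <- setdiff(c(factors, group_vars), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  grouped <- if (is.null(group_vars)) {
    list(`1` = data)
  } else {
    split(data, interaction(data[group_vars], drop = TRUE, sep = "/"))
  }
  out <- purrr::imap_dfr(grouped, function(sub, key) {
    purrr::map_dfr(factors, function(f) {
      res <- kendall_tau_b(sub[[f]], sub[[response]])
      row <- dplyr::bind_cols(tibble::tibble(factor = f), res)
      if (!is.null(group_vars)) {
        row <- dplyr::bind_cols(sub[1, group_vars, drop = FALSE], row)
      }
      row
    })
  })
  m <- if (family == "within-subset") length(factors) else nrow(out)
  out <- dplyr::mutate(out,
    p_adjusted = pmin(1, .data$p_raw * m),
    significant = .data$p_adjusted < alpha)
  out
}
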