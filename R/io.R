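# Plain-text readers/writers: two-column oxygen traces with '#' metadata
# headers, tab-delimited tables, and JSON fit sidecars.

#' Write an oxygen trace to delimited text
#'
#' Two tab-separated columns (`time_h`, `o2_umol_dm3`) preceded by `#`
#' comment lines carrying the metadata attributes.
#'
#' @param trace Trace data frame (see [fit_trace()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  validate_trace(trace)
  meta <- c(sample_id = attr(trace, "sample_id") %||% NA,
            temperature = attr(trace, "temperature") %||% NA,
            true_linear_rate = attr(trace, "true_linear_rate") %||% NA,
            true_curvature = attr(trace, "true_curvature") %||% NA,
            true_rate_at_deriv = attr(trace, "true_rate_at_deriv") %||% NA)
  header <- sprintf("# %s: %s", names(meta), vapply(meta, format, ""))
  writeLines(c(header, "time_h\to2_umol_dm3"), path)
  readr::write_tsv(setNames(trace[c("time_h", "o2")],
                            c("time_h", "o2_umol_dm3")),
                   path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' Read an oxygen trace from delimited text
#'
#' Expects the format written by [write_trace()]: `#` comment lines with
#' `key: value` metadata, then columns `time_h` and `o2_umol_dm3`.
#'
#' @param path File path.
#' @return A trace tibble with metadata restored as attributes.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  tab <- readr::read_tsv(I(lines[!grepl("^#", lines)]),
                         col_types = readr::cols(.default = readr::col_double()))
  out <- tibble::tibble(time_h = tab$time_h, o2 = tab$o2_umol_dm3)
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(val))
    attr(out, key) <- if (is.na(num) && val != "NA") val else num
  }
  validate_trace(out)
  out
}

#' Write a table as tab-delimited text
#'
#' UTF-8, tab-delimited, with a versioned `#` header line for provenance.
#'
#' @param x Data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  writeLines(sprintf("# pirtfield table v1 (%d rows)", nrow(x)), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a tab-delimited table written by [write_table()]
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Write a maintenance-model fit as a JSON sidecar
#'
#' @param fit A `pirt_fit` (or named list of them, as from
#'   `fit_pirt(form = "both")`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  as_rec <- function(f) list(
    form = f$form, rm = f$rm, b = f$b, r2 = f$r2,
    rm_interval = f$rm_interval, b_interval = f$b_interval,
    n = f$n, interval_method = f$interval_method,
    n_boot = f$n_boot, seed = f$seed)
  rec <- if (inherits(fit, "pirt_fit")) as_rec(fit) else lapply(fit, as_rec)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a maintenance-model fit from its JSON sidecar
#'
#' @param path File path written by [write_fit()].
#' @return A `pirt_fit`, or a named list of them.
#' @export
read_fit <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  from_rec <- function(r) new_pirt_fit(
    r$form, r$rm, r$b, r2 = r$r2 %||% NA_real_,
    rm_interval = unlist(r$rm_interval) %||% c(NA_real_, NA_real_),
    b_interval = unlist(r$b_interval) %||% c(NA_real_, NA_real_),
    n = r$n %||% NA_integer_,
    interval_method = r$interval_method %||% "none",
    seed = r$seed, n_boot = r$n_boot %||% 0L)
  if (!is.null(rec$form)) from_rec(rec) else lapply(rec, from_rec)
}
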