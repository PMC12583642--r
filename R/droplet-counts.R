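#' Construct a single-well droplet classification tally
#'
#' A droplet digital PCR well, after thresholding, reduces to four droplet
#' classes: double-positive (both fluorophores), FAM-only, HEX-only and
#' double-negative. This tally is the raw observable every downstream
#' computation starts from; classification itself (amplitude thresholding)
#' happens upstream in the instrument software.
#'
#' Counts are allowed to be non-integer so that exact *expected* counts
#' (e.g. `n_droplets * p_class`) can be pushed through the same estimators
#' when checking them against closed forms.
#'
#' @param n_total Accepted droplets in the well (>= 1).
#' @param n_double Droplets positive in both channels.
#' @param n_fam_only Droplets positive in FAM only.
#' @param n_hex_only Droplets positive in HEX only.
#' @param n_negative Droplets negative in both channels.
#' @param well_id,sample_id,assay_id Identifier strings.
#'
#' @return An object of class `droplet_counts` (a named list).
#' @examples
#' w <- droplet_counts(20000, n_double = 5000, n_fam_only = 1000,
#'                     n_hex_only = 1200, n_negative = 12800)
#' estimate_lambda(w$n_hex_only + w$n_negative, w$n_total) # FAM concentration
#' @export
droplet_counts <- function(n_total, n_double, n_fam_only, n_hex_only,
                           n_negative,
                           well_id = "A01", sample_id = "sample",
                           assay_id = "assay") {
  x <- structure(
    list(well_id = as.character(well_id),
         sample_id = as.character(sample_id),
         assay_id = as.character(assay_id),
         n_total = as.numeric(n_total),
         n_double = as.numeric(n_double),
         n_fam_only = as.numeric(n_fam_only),
         n_hex_only = as.numeric(n_hex_only),
         n_negative = as.numeric(n_negative)),
    class = "droplet_counts")
  validate_droplet_counts(x)
  x
}

#' Validate a droplet tally against its class-sum and sign invariants
#'
#' @param x A `droplet_counts` object (or list with the same fields).
#' @param where Optional label (e.g. "row 7") prefixed to error messages.
#' @return `x`, invisibly, if valid; otherwise an error of class
#'   `lociq_input_error`.
#' @export
validate_droplet_counts <- function(x, where = NULL) {
  prefix <- if (is.null(where)) "" else paste0(where, ": ")
  counts <- c(x$n_double, x$n_fam_only, x$n_hex_only, x$n_negative)
  if (any(!is.finite(c(x$n_total, counts)))) {
    abort(paste0(prefix, "droplet counts must be finite numbers"),
          class = "lociq_input_error")
  }
  if (x$n_total < 1) {
    abort(paste0(prefix, "n_total must be >= 1"), class = "lociq_input_error")
  }
  if (any(counts < 0)) {
    abort(paste0(prefix, "droplet class counts must be >= 0"),
          class = "lociq_input_error")
  }
  if (abs(sum(counts) - x$n_total) > 1e-6 * max(1, x$n_total)) {
    abort(paste0(prefix,
                 "droplet classes must sum to n_total (",
                 sum(counts), " != ", x$n_total, ")"),
          class = "lociq_input_error")
  }
  invisible(x)
}

#' @export
print.droplet_counts <- function(x, ...) {
  cat(sprintf(
    "<droplet_counts> well %s | sample %s | assay %s\n", x$well_id,
    x$sample_id, x$assay_id))
  cat(sprintf(
    "  total %s: ++ %s, FAM-only %s, HEX-only %s, -- %s\n",
    format(x$n_total), format(x$n_double), format(x$n_fam_only),
    format(x$n_hex_only), format(x$n_negative)))
  invisible(x)
}

.droplet_csv_cols <- c("well_id", "sample_id", "assay_id", "n_total",
                       "n_double", "n_fam_only", "n_hex_only", "n_negative")

#' Read a droplet-count CSV
#'
#' Expects the exact header
#' `well_id,sample_id,assay_id,n_total,n_double,n_fam_only,n_hex_only,n_negative`
#' (UTF-8, comma-separated, one row per well). Every row is validated
#' against the droplet-tally invariants; offending rows are reported with
#' their row number.
#'
#' @param path CSV file path.
#' @return A tibble with one row per well.
#' @export
read_droplet_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!identical(names(df), .droplet_csv_cols)) {
    abort(paste0("droplet CSV header must be exactly: ",
                 paste(.droplet_csv_cols, collapse = ",")),
          class = "lociq_input_error")
  }
  validate_droplet_table(df)
  df
}

#' Validate a droplet-count table row by row
#'
#' @param df Data frame in the droplet CSV layout.
#' @return `df`, invisibly; errors carry row numbers.
#' @export
validate_droplet_table <- function(df) {
  missing <- setdiff(.droplet_csv_cols, names(df))
  if (length(missing)) {
    abort(paste0("droplet table lacks columns: ",
                 paste(missing, collapse = ", ")),
          class = "lociq_input_error")
  }
  errors <- character(0)
  for (i in seq_len(nrow(df))) {
    row <- as.list(df[i, ])
    ok <- tryCatch({
      validate_droplet_counts(row, where = paste0("row ", i))
      NULL
    }, lociq_input_error = function(e) conditionMessage(e))
    if (!is.null(ok)) errors <- c(errors, ok)
  }
  if (length(errors)) {
    abort(paste(c("invalid droplet rows:", errors), collapse = "\n  "),
          class = "lociq_input_error")
  }
  invisible(df)
}

#' Write a droplet-count table in the package's CSV dialect
#'
#' @param df Data frame with the droplet CSV columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_droplet_csv <- function(df, path) {
  readr::write_csv(df[, .droplet_csv_cols], path, progress = FALSE)
  invisible(path)
}

# Coerce one row of a droplet table to droplet_counts.
.row_to_counts <- function(row) {
  droplet_counts(row$n_total, row$n_double, row$n_fam_only, row$n_hex_only,
                 row$n_negative, well_id = row$well_id,
                 sample_id = row$sample_id, assay_id = row$assay_id)
}
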