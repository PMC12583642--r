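#' Limit of blank for a reference-normalised measurement
#'
#' The one-sided 95% upper bound on what a blank (mutation-free) sample
#' produces: `LoB = mean + 1.645 * sd` over replicate blank measurements,
#' with the sample (n-1) standard deviation. A single future blank
#' measurement exceeds this bound about 5% of the time.
#'
#' @param blank_values At least two reference-normalised blank
#'   measurements.
#' @return The limit of blank, on the same scale as the inputs.
#' @examples
#' limit_of_blank(c(rep(1, 19), 1)) # sd 0 -> LoB = 1
#' @export
limit_of_blank <- function(blank_values) {
  blank_values <- blank_values[is.finite(blank_values)]
  if (length(blank_values) < 2) {
    abort("limit_of_blank needs >= 2 blank measurements",
          class = "lociq_input_error")
  }
  mean(blank_values) + 1.645 * sd(blank_values)
}

#' Construct a dilution series from expected and observed fractions
#'
#' @param level_expected True mutant fractions per measurement, in
#'   `[0, 1]`.
#' @param observed Matched reference-normalised, dilution-corrected
#'   measurements.
#' @param replicate Optional replicate index per measurement.
#' @return A `dilution_series` tibble, sorted by descending level.
#' @export
dilution_series <- function(level_expected, observed, replicate = NULL) {
  if (length(level_expected) != length(observed)) {
    abort("level_expected and observed must have equal length",
          class = "lociq_input_error")
  }
  if (any(level_expected < 0 | level_expected > 1, na.rm = TRUE)) {
    abort("expected fractions must lie in [0, 1]",
          class = "lociq_input_error")
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(level_expected), level_expected,
                            FUN = seq_along)
  }
  out <- tibble::tibble(level_expected = level_expected,
                        replicate = as.integer(replicate),
                        observed = observed)
  out <- out[order(-out$level_expected, out$replicate), ]
  class(out) <- c("dilution_series", class(out))
  out
}

#' Read a dilution-series CSV (`level_expected,replicate,observed`)
#'
#' @param path CSV path.
#' @return A [dilution_series()].
#' @export
read_dilution_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("level_expected", "replicate", "observed")
  if (!all(need %in% names(df))) {
    abort(paste0("dilution CSV must carry columns: ",
                 paste(need, collapse = ",")),
          class = "lociq_input_error")
  }
  dilution_series(df$level_expected, df$observed, df$replicate)
}

#' Limit of detection from a dilution series
#'
#' `LoD = LoB + 1.645 * sd(lowest level above LoB)`: the lowest dilution
#' level whose mean observed fraction exceeds the limit of blank
#' contributes its replicate standard deviation, again as a one-sided 95%
#' construction. The linearity of the series is summarised by the
#' regression of observed on expected fractions.
#'
#' @param lob Limit of blank, from [limit_of_blank()].
#' @param series A [dilution_series()] (levels with expected fraction 0
#'   are ignored for the LoD but kept in the regression).
#' @return A list: `lod`, `lob`, `lowest_level` (expected fraction used),
#'   `slope`, `intercept`, `r2`.
#' @export
limit_of_detection <- function(lob, series) {
  stopifnot(is.data.frame(series))
  lv <- dplyr::summarise(
    dplyr::group_by(series[series$level_expected > 0, ], .data$level_expected),
    mean_obs = mean(.data$observed), sd_obs = sd(.data$observed),
    .groups = "drop")
  above <- lv[lv$mean_obs > lob, ]
  if (!nrow(above)) {
    abort("no dilution level detected above the limit of blank",
          class = "lociq_detection_failure")
  }
  lowest <- above[which.min(above$level_expected), ]
  sd_low <- if (is.na(lowest$sd_obs)) 0 else lowest$sd_obs
  fit <- lm(observed ~ level_expected, data = series)
  list(lod = lob + 1.645 * sd_low, lob = lob,
       lowest_level = lowest$level_expected,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = summary(fit)$r.squared)
}

#' Detection-limit report for a blank set and dilution series
#'
#' Convenience wrapper producing the JSON-ready report
#' `{lob, lod, slope, intercept, r2}`.
#'
#' @param blank_values Blank measurements (see [limit_of_blank()]).
#' @param series A [dilution_series()].
#' @return A named list.
#' @export
detection_limit_report <- function(blank_values, series) {
  lob <- limit_of_blank(blank_values)
  lod <- limit_of_detection(lob, series)
  list(lob = lob, lod = lod$lod, slope = lod$slope,
       intercept = lod$intercept, r2 = lod$r2)
}
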