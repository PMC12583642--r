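#' Run the absolute-quantification pipeline from file inputs
#'
#' Thin orchestration over [quantify()]: reads the droplet CSV and panel
#' config, writes the tidy per-sample/state summary CSV and returns the
#' result. This and its sibling `run_*()` functions back the `lociq`
#' command-line script (`inst/scripts/lociq.R`).
#'
#' @param config A list (or YAML path) with fields `droplets` (droplet
#'   CSV path), `panel` (panel YAML/JSON path) and optionally `out_dir`
#'   (default `"."`) and `out_file` (default `"summary.csv"`).
#' @return The [quantify()] tibble, invisibly; the CSV lands in
#'   `out_dir`.
#' @export
run_quantify <- function(config) {
  config <- .load_config(config)
  .require_fields(config, c("droplets", "panel"))
  result <- quantify(config$droplets, config$panel)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, config$out_file %||% "summary.csv")
  write_summary_csv(result, path)
  flagged <- unique(result$sample_id[result$flag])
  if (length(flagged)) {
    warn(paste0("state totals outside [90, 110] for sample(s): ",
                paste(flagged, collapse = ", ")))
  }
  invisible(result)
}

#' Fit cleavage/repair kinetics from a timeseries CSV
#'
#' @param config A list (or YAML path) with fields `timeseries` (CSV
#'   path, layout `condition,timepoint_h,replicate,state,percent`), and
#'   optionally `seed` (default 1), `n_boot` (default 1000), `n_starts`
#'   (default 10), `delay_form`, `out_dir`. The fit report
#'   (`fit.json`: coefficients, CIs, R^2) and derived statistics
#'   (`derived.json`, per condition) are written to `out_dir`.
#' @return A list with the [fit_kinetics()] object and the per-condition
#'   [derive_kinetics()] results, invisibly.
#' @export
run_kinetics <- function(config) {
  config <- .load_config(config)
  .require_fields(config, "timeseries")
  fit <- fit_kinetics(
    config$timeseries,
    n_boot = config$n_boot %||% 1000,
    n_starts = config$n_starts %||% 10,
    seed = as.integer(config$seed %||% 1L),
    delay_form = config$delay_form %||% "exp")
  derived <- lapply(fit$coefficients, derive_kinetics)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit_report <- list(
    coefficients = fit$coef_table,
    r2 = as.list(fit$r2), sse = fit$sse,
    settings = fit$settings[c("n_boot", "n_starts", "seed", "fit_ti",
                              "delay_form")])
  jsonlite::write_json(fit_report, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  derived_report <- lapply(derived, function(d) {
    list(K = d$K, half_life_generation = d$half_life_generation,
         half_life_resolution = d$half_life_resolution,
         dsbs_per_product = d$dsbs_per_product,
         likelihood_per_hour = d$likelihood, vmax = d$vmax,
         t_dsb_cum_100 = d$t_dsb_cum_100, t_pr_cum_100 = d$t_pr_cum_100)
  })
  jsonlite::write_json(derived_report, file.path(out_dir, "derived.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(config$plot) && requireNamespace("ggplot2", quietly = TRUE)) {
    p <- plot_kinetics_fit(fit)
    ggplot2::ggsave(file.path(out_dir, "fit.pdf"), p, width = 8,
                    height = 5)
  }
  invisible(list(fit = fit, derived = derived))
}

#' Generate a synthetic droplet scenario on disk
#'
#' Simulates droplet wells for an edited sample and its mock control from
#' a declared ground truth, and writes the droplet CSV, the matching
#' panel YAML and a ground-truth sidecar for testing.
#'
#' @param config A list (or YAML path) with optional fields `truth`
#'   (named fractions passed to [locus_ground_truth()]), `n_droplets`
#'   (default 20000), `n_wells` (default 3), `dose_cv` (default 0.02),
#'   `seed` (default 1), `with_donor`, `with_aneu`, `dsb_statistic` and
#'   `out_dir`.
#' @return Named list of written paths (`droplets`, `panel`, `truth`),
#'   invisibly.
#' @export
run_simulate <- function(config = list()) {
  config <- .load_config(config)
  truth_args <- config$truth %||% list(wt = 0.15, indel = 0.40,
                                       large_del_5 = 0.10, dsb = 0.25,
                                       other_loss = 0.10)
  bad <- setdiff(names(truth_args), names(formals(locus_ground_truth)))
  if (length(bad)) {
    abort(paste0("unknown ground-truth field(s): ",
                 paste(bad, collapse = ", ")),
          class = "lociq_config_error")
  }
  truth <- do.call(locus_ground_truth, truth_args)
  panel <- default_panel(
    with_donor = isTRUE(config$with_donor) || truth$ti > 0,
    with_aneu = isTRUE(config$with_aneu),
    dsb_statistic = config$dsb_statistic %||% "min")
  seed <- as.integer(config$seed %||% 1L)
  n_droplets <- config$n_droplets %||% 20000
  n_wells <- config$n_wells %||% 3
  dose_cv <- config$dose_cv %||% 0.02
  mock_truth <- locus_ground_truth(wt = 1, ploidy = truth$ploidy,
                                   cells_assayed = truth$cells_assayed)
  droplets <- dplyr::bind_rows(
    simulate_sample_wells(mock_truth, panel, sample_id = "mock",
                          n_droplets = n_droplets, n_wells = n_wells,
                          seed = seed, dose_cv = dose_cv),
    simulate_sample_wells(truth, panel, sample_id = "edited",
                          n_droplets = n_droplets, n_wells = n_wells,
                          seed = seed + 1L, dose_cv = dose_cv))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(droplets = file.path(out_dir, "droplets.csv"),
                panel = file.path(out_dir, "panel.yaml"),
                truth = file.path(out_dir, "truth.yaml"))
  write_droplet_csv(droplets, paths$droplets)
  write_panel_config(panel, paths$panel)
  yaml::write_yaml(c(unclass(truth), list(seed = seed)), paths$truth)
  invisible(paths)
}

#' Detection-limit report from a dilution CSV
#'
#' @param config A list (or YAML path) with field `dilution` (CSV path,
#'   layout `level_expected,replicate,observed`) and optionally `blanks`
#'   (numeric vector or path to a one-column CSV of blank measurements;
#'   defaults to the series' zero-level observations) and `out_dir`.
#' @return The report list (`lob, lod, slope, intercept, r2`), invisibly;
#'   written as `detection_limits.json`.
#' @export
run_lod <- function(config) {
  config <- .load_config(config)
  .require_fields(config, "dilution")
  series <- read_dilution_csv(config$dilution)
  blanks <- config$blanks
  if (is.null(blanks)) {
    blanks <- series$observed[series$level_expected == 0]
  } else if (is.character(blanks)) {
    blanks <- readr::read_csv(blanks, show_col_types = FALSE,
                              progress = FALSE)[[1]]
  }
  report <- detection_limit_report(blanks, series)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report,
                       file.path(out_dir, "detection_limits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

.load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) {
    abort("config must be a list or a YAML path",
          class = "lociq_config_error")
  }
  config
}

.require_fields <- function(config, fields) {
  missing <- fields[!fields %in% names(config)]
  if (length(missing)) {
    abort(paste0("config lacks required field(s): ",
                 paste(missing, collapse = ", ")),
          class = "lociq_config_error")
  }
  invisible(config)
}
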