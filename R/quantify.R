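#' Quantify locus-integrity states for every sample of a droplet table
#'
#' Runs the full absolute-quantification pipeline: per-well Poisson copy
#' and linkage estimation, double normalisation of every mutation assay
#' against the reference assays and the mock control, and combination
#' into one locus-integrity summary per sample.
#'
#' @param droplets Droplet-count table (see [read_droplet_csv()]) or path
#'   to a droplet CSV.
#' @param panel An [assay_panel()] or path to a panel YAML/JSON.
#' @return A tibble, one row per sample x state
#'   (`sample_id, condition, timepoint_h, state, percent, sd, flag`),
#'   covering the six stacked states plus `trim5`, `trim3` and — when the
#'   panel carries the assays — `aneu_p_change`, `aneu_q_change`. The full
#'   [combine_summary()] objects are attached as attribute `"summaries"`.
#' @export
quantify <- function(droplets, panel) {
  if (is.character(droplets)) droplets <- read_droplet_csv(droplets)
  if (is.character(panel)) panel <- read_panel_config(panel)
  validate_droplet_table(droplets)
  validate_assay_panel(panel)

  unknown <- setdiff(unique(droplets$assay_id), panel$assays$id)
  if (length(unknown)) {
    abort(paste0("droplet table contains assays absent from the panel: ",
                 paste(unknown, collapse = ", ")),
          class = "lociq_config_error")
  }
  unknown_s <- setdiff(unique(droplets$sample_id), panel$samples$id)
  if (length(unknown_s)) {
    abort(paste0("droplet table contains samples absent from the panel: ",
                 paste(unknown_s, collapse = ", ")),
          class = "lociq_config_error")
  }

  # wells for (sample, role), as replicate-ordered droplet_counts lists
  wells_for <- function(sample, role) {
    ids <- panel$assays$id[panel$assays$role == role]
    rows <- droplets[droplets$sample_id == sample &
                       droplets$assay_id %in% ids, ]
    if (!nrow(rows)) return(NULL)
    rows <- rows[order(rows$assay_id, rows$well_id), ]
    lapply(seq_len(nrow(rows)), function(i) .row_to_counts(rows[i, ]))
  }

  mock_id <- panel$mock_sample
  mock_ref <- wells_for(mock_id, "reference")
  if (is.null(mock_ref)) {
    abort("no reference wells found for the mock sample",
          class = "lociq_config_error")
  }
  mock_edge <- wells_for(mock_id, "edge")
  mock_flank <- wells_for(mock_id, "flanking")
  mock_aneu <- wells_for(mock_id, "aneu")
  mock_donor <- wells_for(mock_id, "donor_total")

  flank_row <- panel$assays[panel$assays$role == "flanking", ]
  flank_distance <- if (nrow(flank_row)) {
    d <- flank_row$distance_bp[1]
    if (is.na(d)) 50 else d
  } else 50

  summaries <- list()
  for (sample in panel$samples$id) {
    meta <- panel$samples[panel$samples$id == sample, ]
    ref <- wells_for(sample, "reference")
    if (is.null(ref)) {
      abort(paste0("no reference wells for sample '", sample, "'"),
            class = "lociq_config_error")
    }
    edge_wells <- wells_for(sample, "edge")
    if (is.null(edge_wells) || is.null(mock_edge)) {
      abort(paste0("edge wells missing for sample '", sample,
                   "' or the mock"),
            class = "lociq_config_error")
    }
    edge <- edge_summary(edge_wells, ref, mock_edge, mock_ref)

    flanking <- NULL
    flank_wells <- wells_for(sample, "flanking")
    if (!is.null(flank_wells) && !is.null(mock_flank) &&
        panel$flanking_valid) {
      flanking <- flanking_summary(flank_wells, ref, mock_flank, mock_ref,
                                   dsb_statistic = panel$dsb_statistic)
    }

    aneu <- NULL
    aneu_wells <- wells_for(sample, "aneu")
    if (!is.null(aneu_wells) && !is.null(mock_aneu)) {
      aneu <- aneuploidy_summary(aneu_wells, ref, mock_aneu, mock_ref)
    }

    ti <- NULL
    ti_wells <- wells_for(sample, "ti_junction")
    donor_wells <- wells_for(sample, "donor_total")
    if (!is.null(ti_wells) && !is.null(donor_wells) && sample != mock_id) {
      ti <- ti_summary(ti_wells, donor_wells, ref,
                       digested_donor_well =
                         wells_for(sample, "donor_total_digested"),
                       mock_donor_well = mock_donor,
                       ploidy = panel$ploidy)
    }

    summaries[[sample]] <- combine_summary(
      edge, flanking, aneu, ti,
      flank_distance_bp = flank_distance,
      large_del_threshold_bp = panel$large_del_threshold_bp,
      sample_id = sample, condition = meta$condition,
      timepoint_h = meta$timepoint_h)
  }

  out <- dplyr::bind_rows(lapply(summaries, summary_to_rows))
  attr(out, "summaries") <- summaries
  out
}

#' Flatten a locus-integrity summary to tidy rows
#'
#' @param s A [combine_summary()] result.
#' @return A tibble `sample_id, condition, timepoint_h, state, percent,
#'   sd, flag`.
#' @export
summary_to_rows <- function(s) {
  extra <- tibble::tibble(
    state = c("trim5", "trim3", "aneu_p_change", "aneu_q_change"),
    percent = c(s$trim5, s$trim3, s$aneu_p_change, s$aneu_q_change),
    sd = NA_real_)
  extra <- extra[!is.na(extra$percent), ]
  rows <- dplyr::bind_rows(s$states, extra)
  tibble::tibble(sample_id = s$sample_id, condition = s$condition,
                 timepoint_h = s$timepoint_h, state = rows$state,
                 percent = rows$percent, sd = rows$sd, flag = s$flag)
}

#' Write a quantification result to CSV
#'
#' @param result Tibble returned by [quantify()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(result, path) {
  readr::write_csv(result, path, progress = FALSE)
  invisible(path)
}
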