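#' Construct an assay-panel configuration
#'
#' The panel declares which assays were run on a locus, what each well's
#' two channels mean, and which sample is the mock-edited (unedited)
#' control used for the second normalisation. Assay roles:
#'
#' * `edge` — one amplicon spanning the cut site; FAM probe over the
#'   cleavage position ("cleavage"), HEX probe ~25 bp away ("distal").
#'   Discriminates wildtype (FAM+HEX), indel (HEX only) and total copy
#'   loss (neither).
#' * `flanking` — two amplicons on either side of the cut site read in one
#'   well: FAM = 5' amplicon, HEX = 3' amplicon. Loss of linkage between
#'   them signals an unresolved DSB; loss of one side's copies signals end
#'   trimming / large deletion.
#' * `flanking5`, `flanking3` — the same amplicons run in separate wells
#'   (FAM channel); trims only, no linkage, so no DSB output.
#' * `reference` (>= 1 required) — probe pair on a non-targeted chromosome
#'   at the same inter-amplicon distance as the flanking assay; the
#'   denominator for copy and linkage normalisation.
#' * `aneu` — sub-telomeric p-arm (FAM) and q-arm (HEX) copy assays.
#' * `ti_junction` — locus/donor junction amplicon (FAM); counts
#'   on-target integrated donors.
#' * `donor_total` — amplicon internal to the donor (FAM); counts all
#'   donor copies, integrated or episomal. `donor_total_digested` is the
#'   same assay after single-cut restriction digestion, for concatemer
#'   detection.
#'
#' @param assays A data frame (or list of lists) with columns `id`, `role`
#'   and optionally `distance_bp` (primer/probe distance from the cut
#'   site, used to label flanking copy loss as trimming vs large
#'   deletion).
#' @param samples A data frame (or list of lists) with columns `id`,
#'   `condition`, `timepoint_h`.
#' @param mock_sample Sample id of the unedited control.
#' @param locus Locus label.
#' @param ploidy Genome copies of the locus per cell (default 2).
#' @param dsb_statistic `"min"` (default) or `"mean"`: how the two flank
#'   copy fractions combine before subtracting the linked fraction (see
#'   the methods vignette for why `min` is the default).
#' @param flanking_valid Set `FALSE` to suppress flanking-derived outputs
#'   (e.g. when an episomal donor carries long homology arms that the
#'   flanking amplicons cannot distinguish from the locus).
#' @param large_del_threshold_bp Probe distance (bp) above which flanking
#'   copy loss is classified as a large deletion rather than trimming
#'   (default 25).
#'
#' @return An `assay_panel` list.
#' @export
assay_panel <- function(assays, samples, mock_sample,
                        locus = "locus", ploidy = 2,
                        dsb_statistic = c("min", "mean"),
                        flanking_valid = TRUE,
                        large_del_threshold_bp = 25) {
  dsb_statistic <- match.arg(dsb_statistic)
  assays <- .as_tibble_of_lists(assays, c("id", "role"))
  if (!"distance_bp" %in% names(assays)) assays$distance_bp <- NA_real_
  samples <- .as_tibble_of_lists(samples, c("id", "condition", "timepoint_h"))
  panel <- structure(
    list(locus = locus, ploidy = ploidy, dsb_statistic = dsb_statistic,
         flanking_valid = flanking_valid,
         large_del_threshold_bp = large_del_threshold_bp,
         assays = assays, samples = samples,
         mock_sample = as.character(mock_sample)),
    class = "assay_panel")
  validate_assay_panel(panel)
  panel
}

.known_roles <- c("edge", "flanking", "flanking5", "flanking3", "reference",
                  "aneu", "aneu_p", "aneu_q", "ti_junction", "donor_total",
                  "donor_total_digested")

.as_tibble_of_lists <- function(x, required) {
  if (is.data.frame(x)) {
    df <- tibble::as_tibble(x)
  } else {
    df <- dplyr::bind_rows(lapply(x, function(e) {
      tibble::as_tibble(e[!vapply(e, is.null, logical(1))])
    }))
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("panel table lacks columns: ",
                 paste(missing, collapse = ", ")),
          class = "lociq_config_error")
  }
  df
}

#' Validate an assay-panel configuration
#'
#' @param panel An [assay_panel()].
#' @return `panel`, invisibly; configuration problems raise
#'   `lociq_config_error`.
#' @export
validate_assay_panel <- function(panel) {
  roles <- panel$assays$role
  bad <- setdiff(roles, .known_roles)
  if (length(bad)) {
    abort(paste0("unknown assay role(s): ", paste(bad, collapse = ", ")),
          class = "lociq_config_error")
  }
  if (!any(roles == "reference")) {
    abort("panel needs at least one reference assay",
          class = "lociq_config_error")
  }
  if (sum(roles == "flanking5") != sum(roles == "flanking3")) {
    abort("flanking5/flanking3 assays must come in pairs",
          class = "lociq_config_error")
  }
  if (anyDuplicated(panel$assays$id)) {
    abort("assay ids must be unique", class = "lociq_config_error")
  }
  if (!panel$mock_sample %in% panel$samples$id) {
    abort("mock_sample must appear in the samples table",
          class = "lociq_config_error")
  }
  if (!is.numeric(panel$ploidy) || panel$ploidy <= 0) {
    abort("ploidy must be a positive number", class = "lociq_config_error")
  }
  invisible(panel)
}

#' @export
print.assay_panel <- function(x, ...) {
  cat(sprintf("<assay_panel> locus %s, ploidy %d, dsb statistic '%s'\n",
              x$locus, x$ploidy, x$dsb_statistic))
  cat(sprintf("  assays: %s\n",
              paste(sprintf("%s(%s)", x$assays$id, x$assays$role),
                    collapse = ", ")))
  cat(sprintf("  samples: %s (mock: %s)\n",
              paste(x$samples$id, collapse = ", "), x$mock_sample))
  invisible(x)
}

#' Read an assay panel from a YAML or JSON file
#'
#' The file carries the fields of [assay_panel()]:
#' ```yaml
#' locus: WAS
#' ploidy: 2
#' dsb_statistic: min
#' flanking_valid: true
#' large_del_threshold_bp: 25
#' mock_sample: mock
#' assays:
#'   - {id: edge1, role: edge, distance_bp: 25}
#'   - {id: flank1, role: flanking, distance_bp: 50}
#'   - {id: ref1, role: reference}
#'   - {id: ref2, role: reference}
#' samples:
#'   - {id: mock, condition: mock, timepoint_h: 72}
#'   - {id: rnp, condition: RNP, timepoint_h: 72}
#' ```
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` panel file.
#' @return An [assay_panel()].
#' @export
read_panel_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (field in c("assays", "samples", "mock_sample")) {
    if (is.null(raw[[field]])) {
      abort(paste0("panel config lacks required field '", field, "'"),
            class = "lociq_config_error")
    }
  }
  assay_panel(
    assays = raw$assays, samples = raw$samples,
    mock_sample = raw$mock_sample,
    locus = raw$locus %||% "locus",
    ploidy = raw$ploidy %||% 2,
    dsb_statistic = raw$dsb_statistic %||% "min",
    flanking_valid = raw$flanking_valid %||% TRUE,
    large_del_threshold_bp = raw$large_del_threshold_bp %||% 25)
}

#' Write an assay panel to YAML
#'
#' @param panel An [assay_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_config <- function(panel, path) {
  out <- list(
    locus = panel$locus, ploidy = panel$ploidy,
    dsb_statistic = panel$dsb_statistic,
    flanking_valid = panel$flanking_valid,
    large_del_threshold_bp = panel$large_del_threshold_bp,
    mock_sample = panel$mock_sample,
    assays = lapply(seq_len(nrow(panel$assays)), function(i) {
      a <- as.list(panel$assays[i, ])
      if (is.na(a$distance_bp)) a$distance_bp <- NULL
      a
    }),
    samples = lapply(seq_len(nrow(panel$samples)),
                     function(i) as.list(panel$samples[i, ])))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' A ready-made two-condition panel for simulation and examples
#'
#' Edge + dual-probe flanking + two reference assays, one edited sample
#' and a mock control; optionally the donor assays.
#'
#' @param with_donor Include `ti_junction` and `donor_total` assays.
#' @param with_aneu Include the sub-telomeric arm assay.
#' @param dsb_statistic Passed to [assay_panel()].
#' @return An [assay_panel()].
#' @export
default_panel <- function(with_donor = FALSE, with_aneu = FALSE,
                          dsb_statistic = "min") {
  assays <- list(
    list(id = "edge1", role = "edge", distance_bp = 25),
    list(id = "flank1", role = "flanking", distance_bp = 50),
    list(id = "ref1", role = "reference"),
    list(id = "ref2", role = "reference"))
  if (with_aneu) assays <- c(assays, list(list(id = "aneu1", role = "aneu")))
  if (with_donor) {
    assays <- c(assays,
                list(list(id = "ti1", role = "ti_junction"),
                     list(id = "donor1", role = "donor_total")))
  }
  assay_panel(
    assays = assays,
    samples = list(
      list(id = "mock", condition = "mock", timepoint_h = 72),
      list(id = "edited", condition = "RNP", timepoint_h = 72)),
    mock_sample = "mock",
    dsb_statistic = dsb_statistic)
}
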