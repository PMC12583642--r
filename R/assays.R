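#' Double normalisation of an assay copy number
#'
#' The first normalisation divides an assay's copy number by the averaged
#' reference-assay copies of the same sample, cancelling gDNA input dose.
#' The second divides that ratio by the same ratio formed in the
#' mock-edited control, cancelling assay-specific amplification
#' differences. The result is a dimensionless fraction of loci on a scale
#' where the unedited state is exactly 1.
#'
#' @param assay_copies Assay copy number(s) (>= 0); a vector is treated as
#'   technical replicates.
#' @param ref_copies Reference-assay copies of the same sample (numeric
#'   vector, one value per reference assay), averaged before dividing.
#' @param mock_assay_copies The same assay's copies in the mock control
#'   (> 0).
#' @param mock_ref_copies Reference copies in the mock control (> 0).
#' @return A `normalised_fraction` list: `value` (mean over replicates),
#'   `sd` (NA for a single value), `n_replicates`, `values`
#'   (per-replicate fractions).
#' @examples
#' double_normalise(4000, c(8000, 8000), 9000, c(9000, 9000))$value # 0.5
#' @export
double_normalise <- function(assay_copies, ref_copies, mock_assay_copies,
                             mock_ref_copies) {
  if (any(assay_copies < 0) || any(!is.finite(assay_copies))) {
    abort("assay_copies must be finite and >= 0",
          class = "lociq_input_error")
  }
  if (!length(ref_copies) || !length(mock_ref_copies)) {
    abort("reference copy lists must be non-empty",
          class = "lociq_input_error")
  }
  if (any(c(ref_copies, mock_assay_copies, mock_ref_copies) <= 0) ||
      any(!is.finite(c(ref_copies, mock_assay_copies, mock_ref_copies)))) {
    abort("reference and mock copies must be finite and > 0",
          class = "lociq_input_error")
  }
  values <- (assay_copies / mean(ref_copies)) /
    (mean(mock_assay_copies) / mean(mock_ref_copies))
  structure(
    list(value = mean(values),
         sd = if (length(values) > 1) sd(values) else NA_real_,
         n_replicates = length(values), values = values),
    class = "normalised_fraction")
}

# ---- replicate plumbing -----------------------------------------------

.as_well_list <- function(x) {
  if (inherits(x, "droplet_counts")) list(x) else x
}

# Per-replicate reference copies: group reference wells by assay, take the
# two-channel mean per well, pair replicates across assays by order, and
# average across reference assays within each replicate.
.ref_copies_per_rep <- function(ref_wells, n_rep = NULL) {
  ref_wells <- .as_well_list(ref_wells)
  by_assay <- split(ref_wells,
                    vapply(ref_wells, function(w) w$assay_id, character(1)))
  per_assay <- lapply(by_assay, function(ws) {
    vapply(ws, function(w) {
      cp <- .well_copies(w)
      (cp$fam + cp$hex) / 2
    }, numeric(1))
  })
  nr <- unique(vapply(per_assay, length, integer(1)))
  if (length(nr) != 1) {
    abort("reference assays carry unequal replicate counts",
          class = "lociq_input_error")
  }
  if (!is.null(n_rep) && nr != n_rep) {
    abort("reference and assay wells carry unequal replicate counts",
          class = "lociq_input_error")
  }
  rowMeans(do.call(cbind, per_assay))
}

# Per-replicate linked reference copies (for linkage normalisation).
.ref_linked_per_rep <- function(ref_wells) {
  ref_wells <- .as_well_list(ref_wells)
  by_assay <- split(ref_wells,
                    vapply(ref_wells, function(w) w$assay_id, character(1)))
  per_assay <- lapply(by_assay, function(ws) {
    vapply(ws, function(w) .well_copies(w)$linked, numeric(1))
  })
  rowMeans(do.call(cbind, per_assay))
}

.channel_copies_per_rep <- function(wells, channel) {
  vapply(.as_well_list(wells), function(w) .well_copies(w)[[channel]],
         numeric(1))
}

# Double-normalised per-replicate series: each sample replicate against
# its replicate-paired reference, divided by the mock's mean ratio.
.dn_values <- function(assay_copies, ref_copies, mock_assay_copies,
                       mock_ref_copies) {
  if (any(c(ref_copies, mock_ref_copies) <= 0) ||
      mean(mock_assay_copies) <= 0) {
    abort("reference and mock copies must be > 0 for normalisation",
          class = "lociq_input_error")
  }
  (assay_copies / ref_copies) /
    (mean(mock_assay_copies) / mean(mock_ref_copies))
}

.state_row <- function(state, values) {
  tibble::tibble(state = state, percent = mean(values),
                 sd = if (length(values) > 1) sd(values) else NA_real_,
                 n_replicates = length(values))
}

# ---- assay summaries ---------------------------------------------------

#' Edge-assay summary: wildtype, indel and total-copy-loss fractions
#'
#' The FAM (cleavage) probe only reports loci with an intact cut site, so
#' its double-normalised fraction is the wildtype percentage. The HEX
#' (distal) probe also reports indel-bearing loci, so the FAM-HEX gap is
#' the indel percentage. Loci lost to both channels (large deletions,
#' unresolved DSBs, rearrangements) appear as the remaining copy loss.
#'
#' @param edge_well Edge-assay well(s); a list is treated as technical
#'   replicates.
#' @param ref_wells Reference well(s) for the same sample.
#' @param mock_edge_well,mock_ref_wells The same assays in the mock
#'   control.
#' @return A tibble with rows `wt`, `indel`, `other` (percent, sd,
#'   n_replicates), with per-replicate fractions in attribute
#'   `"replicates"`.
#' @export
edge_summary <- function(edge_well, ref_wells, mock_edge_well,
                         mock_ref_wells) {
  edge_well <- .as_well_list(edge_well)
  mock_edge_well <- .as_well_list(mock_edge_well)
  ref <- .ref_copies_per_rep(ref_wells, n_rep = length(edge_well))
  mock_ref <- .ref_copies_per_rep(mock_ref_wells)
  f_fam <- .dn_values(.channel_copies_per_rep(edge_well, "fam"), ref,
                      mean(.channel_copies_per_rep(mock_edge_well, "fam")),
                      mean(mock_ref))
  f_hex <- .dn_values(.channel_copies_per_rep(edge_well, "hex"), ref,
                      mean(.channel_copies_per_rep(mock_edge_well, "hex")),
                      mean(mock_ref))
  out <- dplyr::bind_rows(
    .state_row("wt", 100 * f_fam),
    .state_row("indel", 100 * pmax(0, f_hex - f_fam)),
    .state_row("other", 100 * pmax(0, 1 - f_hex)))
  attr(out, "replicates") <- list(f_fam = f_fam, f_hex = f_hex)
  out
}

#' Flanking-assay summary: end trimming, large deletions and DSBs
#'
#' Copy loss on one side of the cut (the 5' FAM or 3' HEX amplicon)
#' reports end trimming / large deletions in that direction. Linkage loss
#' between the two sides, measured from the excess of double-positive
#' droplets and double-normalised like any copy number, reports loci whose
#' two flanks no longer sit on one molecule: unresolved DSBs.
#'
#' The DSB statistic subtracts the linked fraction from the surviving
#' flank fractions. With `dsb_statistic = "min"` (default) the smaller
#' flank fraction is used, so loci that lost a flank entirely (one-sided
#' deletions) do not inflate the DSB estimate through their surviving free
#' flank; `"mean"` uses the average of the two sides, symmetric but
#' confounded by one-sided loss (see the methods vignette).
#'
#' @param flank_well Dual-probe flanking well(s): FAM = 5' amplicon,
#'   HEX = 3' amplicon.
#' @param ref_wells,mock_flank_well,mock_ref_wells As in [edge_summary()].
#' @param dsb_statistic `"min"` or `"mean"`.
#' @return A tibble with rows `trim5`, `trim3`, `dsb`, `linked` (percent).
#' @export
flanking_summary <- function(flank_well, ref_wells, mock_flank_well,
                             mock_ref_wells,
                             dsb_statistic = c("min", "mean")) {
  dsb_statistic <- match.arg(dsb_statistic)
  flank_well <- .as_well_list(flank_well)
  mock_flank_well <- .as_well_list(mock_flank_well)
  ref <- .ref_copies_per_rep(ref_wells, n_rep = length(flank_well))
  mock_ref <- .ref_copies_per_rep(mock_ref_wells)
  f5 <- .dn_values(.channel_copies_per_rep(flank_well, "fam"), ref,
                   mean(.channel_copies_per_rep(mock_flank_well, "fam")),
                   mean(mock_ref))
  f3 <- .dn_values(.channel_copies_per_rep(flank_well, "hex"), ref,
                   mean(.channel_copies_per_rep(mock_flank_well, "hex")),
                   mean(mock_ref))
  f_link <- .dn_values(
    .channel_copies_per_rep(flank_well, "linked"), ref,
    mean(.channel_copies_per_rep(mock_flank_well, "linked")),
    mean(mock_ref))
  f_both <- if (dsb_statistic == "min") pmin(f5, f3) else (f5 + f3) / 2
  out <- dplyr::bind_rows(
    .state_row("trim5", 100 * pmax(0, 1 - f5)),
    .state_row("trim3", 100 * pmax(0, 1 - f3)),
    .state_row("dsb", 100 * pmax(0, f_both - f_link)),
    .state_row("linked", 100 * f_link))
  attr(out, "replicates") <- list(f5 = f5, f3 = f3, f_link = f_link)
  out
}

#' Aneuploidy summary: signed p-/q-arm copy-number change
#'
#' Sub-telomeric arm assays double-normalise like any copy number; the
#' change relative to the mock (in percent, negative = loss, positive =
#' gain) reports arm-level aneuploidy. Balanced segregated translocations
#' can surface as a gain.
#'
#' @param aneu_well Arm-assay well(s): FAM = p arm, HEX = q arm.
#' @param ref_wells,mock_aneu_well,mock_ref_wells As in [edge_summary()].
#' @return A tibble with rows `aneu_p_change`, `aneu_q_change` (signed
#'   percent).
#' @export
aneuploidy_summary <- function(aneu_well, ref_wells, mock_aneu_well,
                               mock_ref_wells) {
  aneu_well <- .as_well_list(aneu_well)
  mock_aneu_well <- .as_well_list(mock_aneu_well)
  ref <- .ref_copies_per_rep(ref_wells, n_rep = length(aneu_well))
  mock_ref <- .ref_copies_per_rep(mock_ref_wells)
  f_p <- .dn_values(.channel_copies_per_rep(aneu_well, "fam"), ref,
                    mean(.channel_copies_per_rep(mock_aneu_well, "fam")),
                    mean(mock_ref))
  f_q <- .dn_values(.channel_copies_per_rep(aneu_well, "hex"), ref,
                    mean(.channel_copies_per_rep(mock_aneu_well, "hex")),
                    mean(mock_ref))
  out <- dplyr::bind_rows(
    .state_row("aneu_p_change", 100 * (f_p - 1)),
    .state_row("aneu_q_change", 100 * (f_q - 1)))
  attr(out, "replicates") <- list(f_p = f_p, f_q = f_q)
  out
}

#' Targeted-integration and episomal-donor summary
#'
#' Donor assays have no counterpart in the mock (which carries no donor),
#' so they are normalised against the reference copies only. The junction
#' assay counts on-target integrated donors as a percentage of loci; the
#' donor-total assay counts every donor copy, so its excess over the
#' integrated copies is the episomal pool. Donor copy number per cell
#' (VCN) uses the configured ploidy; when a single-cut-digested
#' donor-total well is supplied, the VCN ratio digested/undigested reports
#' concatemers (a ratio of ~1 means none formed).
#'
#' @param ti_well Junction-assay well(s), FAM channel.
#' @param donor_total_well Donor-total well(s), FAM channel.
#' @param ref_wells Reference well(s) of the same sample.
#' @param digested_donor_well Optional donor-total well(s) after
#'   single-cut restriction digestion.
#' @param mock_donor_well Optional donor-total well(s) from the mock; any
#'   donor signal there triggers a contamination warning.
#' @param ploidy Locus copies per cell (default 2).
#' @return A tibble with rows `targeted_integration` (percent of loci),
#'   `episomal_fraction` (percent of donor copies), plus scalar attributes
#'   `vcn`, `episomal_copies`, `concatemer_ratio`.
#' @export
ti_summary <- function(ti_well, donor_total_well, ref_wells,
                       digested_donor_well = NULL, mock_donor_well = NULL,
                       ploidy = 2) {
  ti_well <- .as_well_list(ti_well)
  donor_total_well <- .as_well_list(donor_total_well)
  ref <- .ref_copies_per_rep(ref_wells, n_rep = length(ti_well))
  if (!is.null(mock_donor_well)) {
    mock_donor <- mean(.channel_copies_per_rep(mock_donor_well, "fam"))
    if (mock_donor > 0.01 * mean(ref)) {
      warn("donor signal detected in the mock sample: possible contamination")
    }
  }
  junction <- .channel_copies_per_rep(ti_well, "fam")
  donor <- .channel_copies_per_rep(donor_total_well, "fam")
  ti_frac <- junction / ref            # junction copies per locus copy
  vcn_vals <- ploidy * donor / ref
  episomal <- pmax(0, donor - junction)
  episomal_frac <- ifelse(donor > 0, episomal / donor, 0)
  concatemer_ratio <- NA_real_
  if (!is.null(digested_donor_well)) {
    digested <- .channel_copies_per_rep(digested_donor_well, "fam")
    vcn_dig <- ploidy * digested / ref
    concatemer_ratio <- mean(vcn_dig) / mean(vcn_vals)
  }
  out <- dplyr::bind_rows(
    .state_row("targeted_integration", 100 * ti_frac),
    .state_row("episomal_fraction", 100 * episomal_frac))
  attr(out, "vcn") <- mean(vcn_vals)
  attr(out, "episomal_copies") <- mean(episomal)
  attr(out, "concatemer_ratio") <- concatemer_ratio
  attr(out, "replicates") <- list(ti_frac = ti_frac, vcn = vcn_vals,
                                  episomal_copies = episomal)
  out
}

#' Combine assay summaries into a locus-integrity summary
#'
#' Stacks the assay outputs into disjoint state percentages. Flanking copy
#' loss is labelled by the configured primer/probe distance: beyond the
#' large-deletion threshold it stacks as `large_del` (reported per side as
#' `trim5`/`trim3` either way). The edge assay's total copy loss contains
#' the unresolved DSBs, large deletions and integrated donors that the
#' other assays resolve, so those are subtracted (clamped at 0, with
#' clamping recorded) to leave `other` — translocations, inversions and
#' remaining complex lesions.
#'
#' @param edge Output of [edge_summary()].
#' @param flanking Output of [flanking_summary()], or NULL (e.g. when the
#'   panel marks the flanking assay invalid).
#' @param aneuploidy Optional output of [aneuploidy_summary()].
#' @param ti Optional output of [ti_summary()].
#' @param flank_distance_bp Primer/probe distance of the flanking assay.
#' @param large_del_threshold_bp Distance above which flanking copy loss
#'   is a large deletion (default 25).
#' @param sample_id,condition,timepoint_h Metadata carried through.
#' @return A `locus_integrity_summary` list: tibble `states` (one row per
#'   state: percent, sd), `total`, `flag` (TRUE when total falls outside
#'   [90, 110]), `trim5`, `trim3`, `aneu_p_change`, `aneu_q_change`,
#'   `vcn`, `concatemer_ratio`, `clamped`.
#' @export
combine_summary <- function(edge, flanking = NULL, aneuploidy = NULL,
                            ti = NULL, flank_distance_bp = 50,
                            large_del_threshold_bp = 25,
                            sample_id = "sample", condition = NA_character_,
                            timepoint_h = NA_real_) {
  g <- function(tbl, state, col = "percent") {
    if (is.null(tbl)) return(NA_real_)
    v <- tbl[[col]][tbl$state == state]
    if (length(v)) v else NA_real_
  }
  wt <- g(edge, "wt"); indel <- g(edge, "indel")
  edge_other <- g(edge, "other")
  trim5 <- g(flanking, "trim5"); trim3 <- g(flanking, "trim3")
  dsb <- g(flanking, "dsb")
  is_large_del <- isTRUE(flank_distance_bp > large_del_threshold_bp)
  large_del <- if (!is.null(flanking) && is_large_del) {
    max(trim5, trim3)
  } else 0
  ti_pct <- if (is.null(ti)) 0 else g(ti, "targeted_integration")
  dsb_val <- if (is.null(flanking)) 0 else dsb
  other_raw <- edge_other - large_del - dsb_val - ti_pct
  clamped <- is.finite(other_raw) && other_raw < -1e-9
  other <- max(0, other_raw)
  states <- tibble::tibble(
    state = .lociq_states,
    percent = c(wt, indel, large_del, dsb_val, other, ti_pct),
    sd = c(g(edge, "wt", "sd"), g(edge, "indel", "sd"),
           if (is_large_del && !is.null(flanking)) {
             if (trim5 >= trim3) g(flanking, "trim5", "sd")
             else g(flanking, "trim3", "sd")
           } else NA_real_,
           g(flanking, "dsb", "sd"), NA_real_,
           if (is.null(ti)) NA_real_ else g(ti, "targeted_integration", "sd")))
  total <- sum(states$percent, na.rm = TRUE)
  structure(
    list(sample_id = sample_id, condition = condition,
         timepoint_h = timepoint_h, states = states, total = total,
         flag = total < 90 || total > 110,
         trim5 = trim5, trim3 = trim3,
         aneu_p_change = g(aneuploidy, "aneu_p_change"),
         aneu_q_change = g(aneuploidy, "aneu_q_change"),
         vcn = if (is.null(ti)) NA_real_ else attr(ti, "vcn"),
         concatemer_ratio = if (is.null(ti)) NA_real_ else
           attr(ti, "concatemer_ratio"),
         clamped = clamped),
    class = "locus_integrity_summary")
}

#' @export
print.locus_integrity_summary <- function(x, ...) {
  cat(sprintf("<locus_integrity_summary> sample %s (%s, %s h)\n",
              x$sample_id, x$condition, format(x$timepoint_h)))
  for (i in seq_len(nrow(x$states))) {
    cat(sprintf("  %-10s %6.2f%%%s\n", x$states$state[i],
                x$states$percent[i],
                if (is.na(x$states$sd[i])) "" else
                  sprintf(" +/- %.2f", x$states$sd[i])))
  }
  cat(sprintf("  total %.2f%%%s\n", x$total,
              if (x$flag) "  [FLAG: outside 90-110]" else ""))
  invisible(x)
}
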