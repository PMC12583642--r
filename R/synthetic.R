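#' Ground-truth composition of an edited locus population
#'
#' Describes the per-locus state fractions a simulated cell population
#' carries. Fractions may sum to less than 1; the remainder is treated as
#' fully ablated loci (no amplicon survives any assay).
#'
#' @param wt,indel,dsb,ti Fractions of loci that are wildtype, carry a
#'   small indel, sit in an unresolved double-strand break, or carry an
#'   integrated donor.
#' @param large_del_5,large_del_3 Fractions with a large deletion removing
#'   the 5' (resp. 3') flanking amplicon; the deletion spans the cut site,
#'   so the cut-site (edge) amplicon is lost too.
#' @param other_loss Fraction with a local rearrangement (insertion,
#'   inversion, complex lesion) confined between the flanking amplicons:
#'   the cut-site amplicon is destroyed but both flanks survive, still on
#'   one molecule.
#' @param episome_copies_per_cell Free donor-template copies per cell
#'   (episomes), counted by the `donor_total` assay only.
#' @param concatemer_fraction Fraction of episomal donor copies hidden
#'   inside concatemers before digestion: the undigested `donor_total`
#'   assay counts a concatemer once, the digested assay counts every unit.
#' @param aneu_p_change,aneu_q_change Signed fractional change of p-/q-arm
#'   copy number (-0.1 = 10% arm loss).
#' @param ploidy Locus copies per cell (default 2).
#' @param cells_assayed Cells' worth of genomic DNA in each well; total
#'   locus copies = `ploidy * cells_assayed`.
#'
#' @return A `locus_ground_truth` list.
#' @export
locus_ground_truth <- function(wt = 1, indel = 0, large_del_5 = 0,
                               large_del_3 = 0, dsb = 0, other_loss = 0,
                               ti = 0, episome_copies_per_cell = 0,
                               concatemer_fraction = 0,
                               aneu_p_change = 0, aneu_q_change = 0,
                               ploidy = 2, cells_assayed = 8000) {
  fr <- c(wt = wt, indel = indel, large_del_5 = large_del_5,
          large_del_3 = large_del_3, dsb = dsb, other_loss = other_loss,
          ti = ti)
  if (any(fr < 0)) {
    abort("class fractions must be >= 0", class = "lociq_input_error")
  }
  if (sum(fr) > 1 + 1e-9) {
    abort("class fractions must sum to <= 1", class = "lociq_input_error")
  }
  if (cells_assayed < 0) {
    abort("cells_assayed must be >= 0", class = "lociq_input_error")
  }
  structure(
    c(as.list(fr),
      list(episome_copies_per_cell = episome_copies_per_cell,
           concatemer_fraction = concatemer_fraction,
           aneu_p_change = aneu_p_change, aneu_q_change = aneu_q_change,
           ploidy = ploidy, cells_assayed = cells_assayed)),
    class = "locus_ground_truth")
}

# Molecule counts implied by a ground truth for one assay role.
# Returns counts of linked (FAM+HEX on one molecule), free-FAM and
# free-HEX molecules. `shear_prob` converts a linked molecule into a free
# FAM + free HEX pair (random gDNA fragmentation between the probes).
.truth_molecules <- function(truth, role, shear_prob = 0) {
  L <- truth$ploidy * truth$cells_assayed  # total locus copies
  cells <- truth$cells_assayed
  m <- switch(
    role,
    edge = list(
      linked = truth$wt * L,      # FAM (cleavage) + HEX (distal) intact
      fam = 0,
      hex = truth$indel * L),     # FAM probe fails over the indel
    flanking = list(
      # intact around the cut (wt, indel) or rearranged-but-local
      # (other_loss, ti): both flanks present on one molecule
      linked = (truth$wt + truth$indel + truth$other_loss + truth$ti) * L,
      # free 5' flank (FAM): DSB halves and 3'-side deletions
      fam = (truth$dsb + truth$large_del_3) * L,
      # free 3' flank (HEX): DSB halves and 5'-side deletions
      hex = (truth$dsb + truth$large_del_5) * L),
    flanking5 = list(linked = 0,
                     fam = (truth$wt + truth$indel + truth$other_loss +
                              truth$ti + truth$dsb + truth$large_del_3) * L,
                     hex = 0),
    flanking3 = list(linked = 0,
                     fam = (truth$wt + truth$indel + truth$other_loss +
                              truth$ti + truth$dsb + truth$large_del_5) * L,
                     hex = 0),
    reference = list(linked = L, fam = 0, hex = 0),
    aneu = list(linked = 0,
                fam = (1 + truth$aneu_p_change) * L,
                hex = (1 + truth$aneu_q_change) * L),
    ti_junction = list(linked = 0, fam = truth$ti * L, hex = 0),
    donor_total = list(
      linked = 0,
      fam = truth$ti * L +
        truth$episome_copies_per_cell * cells *
          (1 - truth$concatemer_fraction),
      hex = 0),
    donor_total_digested = list(
      linked = 0,
      fam = truth$ti * L + truth$episome_copies_per_cell * cells,
      hex = 0),
    abort(paste0("no molecular model for assay role '", role, "'"),
          class = "lociq_config_error"))
  if (shear_prob > 0 && m$linked > 0) {
    sheared <- m$linked * shear_prob
    m$fam <- m$fam + sheared
    m$hex <- m$hex + sheared
    m$linked <- m$linked - sheared
  }
  m
}

# Closed-form droplet-class probabilities under independent Poisson
# loading of linked, free-FAM and free-HEX molecules.
.droplet_class_probs <- function(lambda_link, lambda_fam, lambda_hex) {
  p_neg <- exp(-(lambda_link + lambda_fam + lambda_hex))
  p_fam_only <- exp(-(lambda_link + lambda_hex)) * (1 - exp(-lambda_fam))
  p_hex_only <- exp(-(lambda_link + lambda_fam)) * (1 - exp(-lambda_hex))
  p_double <- 1 - p_neg - p_fam_only - p_hex_only
  c(double = p_double, fam_only = p_fam_only, hex_only = p_hex_only,
    negative = p_neg)
}

#' Simulate one droplet well from a known locus composition
#'
#' Molecules implied by the ground truth for the assay role are loaded
#' into droplets by independent Poisson placement; each droplet is then
#' classified by its contents. Linked molecules (both probes on one DNA
#' fragment) light up both channels of their droplet, which is what the
#' linkage estimator later inverts. The four-class tally is drawn directly
#' from the closed-form Poisson co-occupancy probabilities, which is
#' distributionally identical to placing molecules one by one.
#'
#' @param truth A [locus_ground_truth()].
#' @param assay_role One of the panel roles (see [assay_panel()]).
#' @param n_droplets Accepted droplets in the well (>= 100).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param expected Return exact expected (real-valued) class counts
#'   instead of a random draw — the noiseless limit used by exactness
#'   tests.
#' @param dose_cv Coefficient of variation of a per-well gDNA dose factor
#'   (lognormal, mean 1), emulating pipetting variability between
#'   replicate wells. Default 0.02.
#' @param shear_prob Per-molecule probability that random fragmentation
#'   separates a linked pair between the probes (default 0).
#' @param well_id,sample_id,assay_id Identifiers for the emitted tally.
#' @return A [droplet_counts()] tally.
#' @export
simulate_droplet_well <- function(truth, assay_role, n_droplets = 20000,
                                  seed = 1L, expected = FALSE,
                                  dose_cv = 0.02, shear_prob = 0,
                                  well_id = "W01", sample_id = "sample",
                                  assay_id = assay_role) {
  stopifnot(inherits(truth, "locus_ground_truth"))
  if (n_droplets < 100) {
    abort("n_droplets must be >= 100", class = "lociq_input_error")
  }
  m <- .truth_molecules(truth, assay_role, shear_prob = shear_prob)
  if (expected) {
    p <- .droplet_class_probs(m$linked / n_droplets, m$fam / n_droplets,
                              m$hex / n_droplets)
    counts <- p * n_droplets
  } else {
    counts <- withr::with_seed(seed, {
      dose <- if (dose_cv > 0) {
        sdl <- sqrt(log(1 + dose_cv^2))
        exp(rnorm(1, -sdl^2 / 2, sdl))
      } else 1
      p <- .droplet_class_probs(dose * m$linked / n_droplets,
                                dose * m$fam / n_droplets,
                                dose * m$hex / n_droplets)
      as.numeric(rmultinom(1, n_droplets, p))
    })
    names(counts) <- c("double", "fam_only", "hex_only", "negative")
  }
  droplet_counts(n_droplets, counts[["double"]], counts[["fam_only"]],
                 counts[["hex_only"]], counts[["negative"]],
                 well_id = well_id, sample_id = sample_id,
                 assay_id = assay_id)
}

#' Simulate replicate droplet wells for every assay of a panel
#'
#' One call per sample: for each assay in the panel, `n_wells` technical
#' replicate wells are simulated from the same ground truth (each with its
#' own dose jitter and droplet sampling).
#'
#' @param truth A [locus_ground_truth()].
#' @param panel An [assay_panel()]; its `assays` table defines which wells
#'   to emit.
#' @param sample_id Sample identifier stamped on the wells.
#' @param n_droplets Droplets per well.
#' @param n_wells Technical replicates per assay (default 3).
#' @param seed Integer seed (per-well seeds are derived from it).
#' @param ... Passed to [simulate_droplet_well()] (`dose_cv`,
#'   `shear_prob`, `expected`).
#' @return A droplet-count tibble in the package's CSV layout.
#' @export
simulate_sample_wells <- function(truth, panel, sample_id = "sample",
                                  n_droplets = 20000, n_wells = 3,
                                  seed = 1L, ...) {
  assays <- panel$assays
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(assays))) {
    for (r in seq_len(n_wells)) {
      k <- k + 1L
      w <- simulate_droplet_well(
        truth, assays$role[i], n_droplets = n_droplets,
        seed = (seed * 10007L + k) %% .Machine$integer.max,
        well_id = sprintf("%s_%s_r%d", sample_id, assays$id[i], r),
        sample_id = sample_id, assay_id = assays$id[i], ...)
      rows[[k]] <- tibble::as_tibble(unclass(w))
    }
  }
  dplyr::bind_rows(rows)[, .droplet_csv_cols]
}

#' Simulate an observed kinetics timeseries from the three-state model
#'
#' Evaluates [simulate_model()] at the requested timepoints and adds
#' independent Gaussian replicate noise (clipped at 0) to the observable
#' states, emulating replicate dPCR summaries along an editing timecourse.
#'
#' @param coeffs A [rate_coefficients()] set for one condition.
#' @param timepoints Hours post-editing (strictly increasing, > 0 allowed
#'   to include 0).
#' @param n_replicates Technical replicates per timepoint (default 3).
#' @param noise_sd Replicate noise, in percentage points (default 2).
#' @param seed Integer seed.
#' @param condition Condition label stamped on the rows.
#' @param states Which observable states to emit (default WT, DSB, IN, LD,
#'   plus TI when `k_ti > 0`).
#' @return A tibble `condition, timepoint_h, replicate, state, percent`.
#' @export
simulate_timeseries <- function(coeffs, timepoints, n_replicates = 3,
                                noise_sd = 2, seed = 1L,
                                condition = "untreated",
                                states = NULL) {
  if (noise_sd < 0) {
    abort("noise_sd must be >= 0", class = "lociq_input_error")
  }
  if (is.null(states)) {
    states <- c("WT", "DSB", "IN", "LD", if (coeffs$k_ti > 0) "TI")
  }
  traj <- simulate_model(coeffs, t_grid = sort(unique(c(0, timepoints))))
  base <- traj[match(timepoints, traj$t), c("t", states)]
  out <- tidyr::expand_grid(timepoint_h = timepoints,
                            replicate = seq_len(n_replicates),
                            state = states)
  out$true_percent <- mapply(function(tp, st) {
    base[[st]][match(tp, base$t)]
  }, out$timepoint_h, out$state)
  noise <- withr::with_seed(seed, rnorm(nrow(out), 0, noise_sd))
  out$percent <- pmax(0, out$true_percent + if (noise_sd > 0) noise else 0)
  tibble::tibble(condition = condition, out[, c("timepoint_h", "replicate",
                                                "state", "percent")])
}

#' Simulate a mutant-fraction dilution series
#'
#' Emulates a serial dilution of a mutant sequence into a wildtype
#' background: observed values are the expected fraction plus Gaussian
#' replicate noise, floored at 0.
#'
#' @param levels True mutant fractions, in `[0, 1]`, descending.
#' @param noise_sd Replicate noise on the fraction scale.
#' @param n_replicates Replicates per level (default 4).
#' @param seed Integer seed.
#' @return A `dilution_series` tibble with columns `level_expected`,
#'   `replicate`, `observed`.
#' @export
simulate_dilution_series <- function(levels, noise_sd = 0.005,
                                     n_replicates = 4, seed = 1L) {
  if (any(levels < 0 | levels > 1)) {
    abort("levels must lie in [0, 1]", class = "lociq_input_error")
  }
  out <- tidyr::expand_grid(level_expected = levels,
                            replicate = seq_len(n_replicates))
  noise <- withr::with_seed(seed, rnorm(nrow(out), 0, noise_sd))
  out$observed <- pmax(0, out$level_expected +
                         if (noise_sd > 0) noise else 0)
  class(out) <- c("dilution_series", class(out))
  out
}
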