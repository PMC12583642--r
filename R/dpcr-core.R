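#' Poisson concentration estimate from negative-droplet counts
#'
#' Molecules distribute over droplets approximately independently, so the
#' count per droplet is Poisson with mean lambda and the fraction of
#' droplets *negative* for a channel estimates `exp(-lambda)`. Inverting
#' gives the standard partition estimator
#' `lambda = ln(n_total / n_negative_in_channel)`.
#'
#' @param n_negative_in_channel Droplets negative in the channel of
#'   interest (for FAM this is `n_hex_only + n_negative`).
#' @param n_total Accepted droplets.
#' @return Mean molecules per droplet (dimensionless), 0 when all droplets
#'   are negative.
#' @examples
#' estimate_lambda(10000, 20000) # ln 2
#' @export
estimate_lambda <- function(n_negative_in_channel, n_total) {
  if (!is.finite(n_negative_in_channel) || !is.finite(n_total) ||
      n_total < 1) {
    abort("counts must be finite and n_total >= 1",
          class = "lociq_input_error")
  }
  if (n_negative_in_channel > n_total) {
    abort("negative-droplet count exceeds total droplets",
          class = "lociq_input_error")
  }
  if (n_negative_in_channel <= 0) {
    abort(paste0("channel saturated: no negative droplets, concentration ",
                 "unquantifiable"),
          class = c("lociq_saturation_error", "lociq_input_error"))
  }
  log(n_total / n_negative_in_channel)
}

#' Linked-molecule concentration from the excess of double positives
#'
#' Two probed sequences residing on the same physical DNA molecule always
#' co-localise in a droplet, so linked molecules inflate the
#' double-positive class above the rate expected by chance from
#' independent loading. With observed negative fractions
#' `f_neg = n_negative/n_total`, `f_Fneg = (n_hex_only + n_negative)/n_total`
#' (FAM-negative) and `f_Hneg = (n_fam_only + n_negative)/n_total`, the
#' three Poisson relations
#' `f_neg = exp(-(lF + lH + lL))`, `f_Fneg = exp(-(lF + lL))`,
#' `f_Hneg = exp(-(lH + lL))` invert in closed form to
#' `lambda_link = ln f_neg - ln f_Fneg - ln f_Hneg`.
#'
#' Sampling noise can push the estimate (or the free-molecule remainders)
#' slightly negative; concentrations are physical non-negatives, so they
#' are floored at 0 and the raw values kept in the result for diagnostics.
#'
#' @param well A [droplet_counts()] tally.
#' @return A `linkage_estimate` list with elements `lambda_link`,
#'   `lambda_fam_free`, `lambda_hex_free`, `lambda_fam`, `lambda_hex`,
#'   `linked_fraction` (= lambda_link / max per-channel lambda) and
#'   `raw` (pre-flooring values).
#' @examples
#' # independence identity: double positives exactly at chance level
#' w <- droplet_counts(10000, 2500, 2500, 2500, 2500)
#' estimate_linkage(w)$lambda_link # 0
#' @export
estimate_linkage <- function(well) {
  validate_droplet_counts(well)
  n <- well$n_total
  n_neg <- well$n_negative
  n_fam_neg <- well$n_hex_only + well$n_negative
  n_hex_neg <- well$n_fam_only + well$n_negative
  if (n_neg <= 0 || n_fam_neg <= 0 || n_hex_neg <= 0) {
    abort("saturated well: a required negative droplet class is empty",
          class = c("lociq_saturation_error", "lociq_input_error"))
  }
  lambda_fam <- log(n / n_fam_neg)
  lambda_hex <- log(n / n_hex_neg)
  link_raw <- log(n_neg / n) - log(n_fam_neg / n) - log(n_hex_neg / n)
  lambda_link <- max(0, link_raw)
  fam_free_raw <- lambda_fam - lambda_link
  hex_free_raw <- lambda_hex - lambda_link
  denom <- max(lambda_fam, lambda_hex)
  structure(
    list(lambda_link = lambda_link,
         lambda_fam_free = max(0, fam_free_raw),
         lambda_hex_free = max(0, hex_free_raw),
         lambda_fam = lambda_fam,
         lambda_hex = lambda_hex,
         linked_fraction = if (denom > 0) min(1, lambda_link / denom) else 0,
         raw = c(lambda_link = link_raw, lambda_fam_free = fam_free_raw,
                 lambda_hex_free = hex_free_raw)),
    class = "linkage_estimate")
}

#' Per-channel absolute copies with bootstrap confidence intervals
#'
#' Point estimates come from [estimate_lambda()]; 95% intervals from a
#' nonparametric bootstrap that resamples the four droplet classes as a
#' multinomial and re-applies the estimator. Absolute copies are reported
#' on the analysed partition set (`copies = lambda * n_total`); all
#' downstream quantities are ratios, so no volume calibration enters.
#'
#' Bootstrap resamples in which a channel loses all its negative droplets
#' are saturated; their lambda is capped at `log(2 * n_total)` so the
#' percentile interval stays finite.
#'
#' @param well A [droplet_counts()] tally.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A `channel_concentration` list with per-channel `lambda`,
#'   `copies`, and 95% `ci_low`/`ci_high` on the lambda scale.
#' @export
copies_with_ci <- function(well, n_boot = 1000, seed = 1L) {
  validate_droplet_counts(well)
  if (n_boot < 1) abort("n_boot must be >= 1", class = "lociq_input_error")
  n <- well$n_total
  counts <- c(well$n_double, well$n_fam_only, well$n_hex_only,
              well$n_negative)
  lambda_fam <- estimate_lambda(counts[3] + counts[4], n)
  lambda_hex <- estimate_lambda(counts[2] + counts[4], n)
  cap <- log(2 * n)
  boot <- withr::with_seed(seed, {
    res <- rmultinom(n_boot, size = round(n), prob = counts / sum(counts))
    fam_neg <- res[3, ] + res[4, ]
    hex_neg <- res[2, ] + res[4, ]
    list(fam = ifelse(fam_neg > 0, log(round(n) / pmax(fam_neg, 1)), cap),
         hex = ifelse(hex_neg > 0, log(round(n) / pmax(hex_neg, 1)), cap))
  })
  ci <- function(v) unname(quantile(v, c(0.025, 0.975), type = 7))
  ci_fam <- ci(boot$fam)
  ci_hex <- ci(boot$hex)
  structure(
    list(lambda_fam = lambda_fam, lambda_hex = lambda_hex,
         copies_fam = lambda_fam * n, copies_hex = lambda_hex * n,
         ci_fam = c(low = ci_fam[1], high = ci_fam[2]),
         ci_hex = c(low = ci_hex[1], high = ci_hex[2]),
         n_total = n, n_boot = n_boot, seed = seed),
    class = "channel_concentration")
}

#' Convert a per-droplet concentration to copies per microlitre
#'
#' Provided for reporting against instrument output; none of the package's
#' summaries depend on it because every assay statistic is a ratio of
#' copies and therefore volume-invariant.
#'
#' @param lambda Mean molecules per droplet.
#' @param partition_volume_nl Droplet volume in nanolitres (default 0.85).
#' @return Copies per microlitre of the analysed reaction.
#' @export
lambda_to_copies_per_ul <- function(lambda, partition_volume_nl = 0.85) {
  lambda / (partition_volume_nl * 1e-3)
}

# Absolute copies for each channel and for linked molecules, used by the
# assay layer. Returns copies on the partition-set scale.
.well_copies <- function(well) {
  n <- well$n_total
  link <- estimate_linkage(well)
  list(fam = link$lambda_fam * n,
       hex = link$lambda_hex * n,
       linked = link$lambda_link * n)
}
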