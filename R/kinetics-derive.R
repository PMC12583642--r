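#' Derived kinetic statistics from fitted rate coefficients
#'
#' Turns a coefficient set (and its trajectory) into the headline
#' quantities of a cleavage/repair analysis:
#'
#' * **Half-lives** — `half_life_generation = ln2 / k_dsb` (time for half
#'   the intact loci to be cut, delay window excluded) and
#'   `half_life_resolution = ln2 / K` with `K` the total resolution rate.
#'   A numerical generation half-life including the delay factor (first
#'   time cumulative cleavages reach half the starting pool) is reported
#'   as a diagnostic.
#' * **DSBs per product** — `K / k_x` for each repair channel: the
#'   average number of cleavage events a locus experiences before ending
#'   in product `x`. The reciprocals over the active channels sum to 1.
#'   Channels with `k_x = 0` are absent from the result, not infinite.
#' * **Per-hour likelihood** — the exact one-hour transition
#'   probabilities of a DSB: `p_x = (k_x / K)(1 - exp(-K))` per channel
#'   and `exp(-K)` unresolved; these sum to 1. With
#'   `likelihood = "conditional"` the split conditional on resolution
#'   (`k_x / K`) is returned instead.
#' * **Event velocities** — `V_max` per event class: the maximum of the
#'   event flux (`k_dsb D(t) WT(t)` for cleavage, `k_x DSB(t)` for
#'   products) over a fine grid, in percent per minute, with the time it
#'   occurs.
#' * **Crossing times** — when cumulative cleavages and cumulative
#'   precise repairs exceed 100% of genome copies, the signature of
#'   recurrent cutting.
#'
#' @param coeffs A [rate_coefficients()] set (one condition).
#' @param trajectory Optional [simulate_model()] trajectory for the same
#'   coefficients; simulated on a fine 24 h grid when omitted.
#' @param likelihood `"per_hour"` (default) or `"conditional"`.
#' @return A `derived_kinetics` list with elements
#'   `half_life_generation`, `half_life_resolution`,
#'   `half_life_generation_numeric`, `dsbs_per_product`, `likelihood`,
#'   `vmax`, `t_dsb_cum_100`, `t_pr_cum_100`, `K`.
#' @examples
#' ck <- rate_coefficients(k_dsb = 0.63, tau = 0.5, k_pr = 0.554,
#'                         k_in = 0.105, k_ld = 0.065)
#' derive_kinetics(ck)$dsbs_per_product
#' @export
derive_kinetics <- function(coeffs, trajectory = NULL,
                            likelihood = c("per_hour", "conditional")) {
  stopifnot(inherits(coeffs, "rate_coefficients"))
  likelihood <- match.arg(likelihood)
  K <- resolution_rate(coeffs)
  if (is.null(trajectory)) {
    trajectory <- simulate_model(coeffs, t_grid = seq(0, 24, by = 0.01))
  }
  wt0 <- trajectory$WT[1] + trajectory$DSB[1]

  channels <- c(precise = coeffs$k_pr, indel = coeffs$k_in,
                large_del = coeffs$k_ld, ti = coeffs$k_ti)
  active <- channels[channels > 0]

  dsbs_per_product <- if (K > 0) as.list(K / active) else list()

  lik <- if (K > 0) {
    if (likelihood == "per_hour") {
      c(as.list((channels / K) * (1 - exp(-K))),
        list(unresolved = exp(-K)))
    } else {
      c(as.list(channels / K), list(unresolved = 0))
    }
  } else {
    list(precise = 0, indel = 0, large_del = 0, ti = 0, unresolved = 1)
  }

  # event fluxes on the trajectory grid, percent/h -> percent/min
  D <- delay_factor(trajectory$t, coeffs$tau, coeffs$delay_form)
  fluxes <- list(
    dsb = coeffs$k_dsb * D * trajectory$WT,
    precise = coeffs$k_pr * trajectory$DSB,
    indel = coeffs$k_in * trajectory$DSB,
    large_del = coeffs$k_ld * trajectory$DSB,
    ti = coeffs$k_ti * trajectory$DSB)
  vmax <- dplyr::bind_rows(lapply(names(fluxes), function(ev) {
    fl <- fluxes[[ev]]
    i <- which.max(fl)
    tibble::tibble(event = ev, vmax_percent_per_min = fl[i] / 60,
                   t_vmax_h = trajectory$t[i])
  }))
  vmax <- vmax[vmax$vmax_percent_per_min > 0, ]

  cross <- function(v) {
    i <- which(v >= 100)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(trajectory$t[1])
    t0 <- trajectory$t[i - 1]; t1 <- trajectory$t[i]
    v0 <- v[i - 1]; v1 <- v[i]
    t0 + (100 - v0) / (v1 - v0) * (t1 - t0)
  }
  gen_half <- function() {
    i <- which(trajectory$DSB_cum >= wt0 / 2)[1]
    if (is.na(i) || i == 1) return(NA_real_)
    t0 <- trajectory$t[i - 1]; t1 <- trajectory$t[i]
    v0 <- trajectory$DSB_cum[i - 1]; v1 <- trajectory$DSB_cum[i]
    t0 + (wt0 / 2 - v0) / (v1 - v0) * (t1 - t0)
  }

  structure(
    list(K = K,
         half_life_generation = if (coeffs$k_dsb > 0)
           log(2) / coeffs$k_dsb else NA_real_,
         half_life_resolution = if (K > 0) log(2) / K else NA_real_,
         half_life_generation_numeric = gen_half(),
         dsbs_per_product = dsbs_per_product,
         likelihood = lik, likelihood_form = likelihood,
         vmax = vmax,
         t_dsb_cum_100 = cross(trajectory$DSB_cum),
         t_pr_cum_100 = cross(trajectory$PR_cum),
         coeffs = coeffs),
    class = "derived_kinetics")
}

#' @export
print.derived_kinetics <- function(x, ...) {
  cat(sprintf("<derived_kinetics> K = %.4g h^-1\n", x$K))
  cat(sprintf("  half-life: generation %.3g h, resolution %.3g h\n",
              x$half_life_generation, x$half_life_resolution))
  if (length(x$dsbs_per_product)) {
    cat("  DSBs per product:",
        paste(sprintf("%s %.3g", names(x$dsbs_per_product),
                      unlist(x$dsbs_per_product)), collapse = ", "), "\n")
  }
  cat("  per-hour likelihood:",
      paste(sprintf("%s %.3g", names(x$likelihood),
                    unlist(x$likelihood)), collapse = ", "), "\n")
  if (!is.na(x$t_dsb_cum_100)) {
    cat(sprintf("  cumulative cleavages pass 100%% at %.3g h\n",
                x$t_dsb_cum_100))
  }
  invisible(x)
}
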