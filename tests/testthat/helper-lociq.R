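# Shared fixtures: everything is generated in code, no data files.

# Expected-count well from exact per-droplet concentrations (the
# noiseless limit of the droplet simulator, used by closed-form checks).
well_from_lambdas <- function(lambda_link, lambda_fam, lambda_hex,
                              n_total = 1e5, ...) {
  p_neg <- exp(-(lambda_link + lambda_fam + lambda_hex))
  p_f <- exp(-(lambda_link + lambda_hex)) * (1 - exp(-lambda_fam))
  p_h <- exp(-(lambda_link + lambda_fam)) * (1 - exp(-lambda_hex))
  p_d <- 1 - p_neg - p_f - p_h
  droplet_counts(n_total, p_d * n_total, p_f * n_total, p_h * n_total,
                 p_neg * n_total, ...)
}

# The reference state mixture used by the end-to-end round trip.
mixture_truth <- function(...) {
  locus_ground_truth(wt = 0.15, indel = 0.40, large_del_5 = 0.10,
                     dsb = 0.25, other_loss = 0.10, ...)
}

mock_truth <- function(...) locus_ground_truth(wt = 1, ...)

# Coefficient sets mirroring an editing experiment with and without
# repair inhibitors.
kin_untreated <- function() {
  rate_coefficients(k_dsb = 0.63, tau = 0.5, k_pr = 0.554, k_in = 0.105,
                    k_ld = 0.065)
}
kin_inhibited <- function() {
  rate_coefficients(k_dsb = 0.63, tau = 0.5, k_pr = 0.1, k_in = 0.005,
                    k_ld = 0.03)
}
kin_timepoints <- function() c(0.5, 1, 2, 3, 4, 6, 8, 10, 12, 16, 20, 24)

# Two-condition observed timeseries from the reference coefficient sets.
kin_observed <- function(noise_sd = 0, seed = 1L,
                         tp = kin_timepoints()) {
  dplyr::bind_rows(
    simulate_timeseries(kin_untreated(), tp, noise_sd = noise_sd,
                        seed = seed, condition = "untreated"),
    simulate_timeseries(kin_inhibited(), tp, noise_sd = noise_sd,
                        seed = seed + 1000L, condition = "inhibited"))
}

# Random valid coefficient sets for property-style loops.
random_coeffs <- function(n, seed = 42L) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      rate_coefficients(
        k_dsb = runif(1, 0.05, 3), tau = runif(1, 0, 2),
        k_pr = runif(1, 0, 1.5), k_in = runif(1, 0, 0.5),
        k_ld = runif(1, 0, 0.3), k_ti = runif(1, 0, 0.2))
    })
  })
}
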