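test_that("zero coefficients freeze the system at its initial state", {
  tr <- simulate_model(rate_coefficients(k_dsb = 0), t_grid = 0:24)
  expect_true(all(tr$WT == 100))
  expect_true(all(tr$DSB == 0 & tr$IN == 0 & tr$DSB_cum == 0))
})

test_that("the equal-rate linear chain matches its closed form", {
  # tau = 0, k_dsb = k_in = 1/h, no precise repair
  tr <- simulate_model(rate_coefficients(k_dsb = 1, k_in = 1),
                       t_grid = seq(0, 5, by = 0.25))
  t <- tr$t
  expect_equal(tr$WT, 100 * exp(-t), tolerance = 1e-9)
  expect_equal(tr$DSB, 100 * t * exp(-t), tolerance = 1e-9)
  expect_equal(tr$IN, 100 * (1 - exp(-t) * (1 + t)), tolerance = 1e-9)
  expect_lt(max(abs(tr$WT[t == 1] - 100 * exp(-1))), 1e-6)
})

test_that("state conservation holds to 1e-6 for random coefficient sets", {
  for (ck in random_coeffs(100)) {
    tr <- simulate_model(ck, t_grid = seq(0, 24, by = 2), dt = 0.01)
    expect_lt(max(abs(tr$WT + tr$DSB + tr$IN + tr$LD + tr$TI - 100)),
              1e-6)
    expect_true(all(diff(tr$DSB_cum) >= -1e-12))
    expect_true(all(diff(tr$PR_cum) >= -1e-12))
  }
})

test_that("trajectories agree with an independent high-accuracy integrator", {
  skip_if_not_installed("deSolve")
  for (ck in random_coeffs(5, seed = 99)) {
    rhs <- function(t, y, p) {
      D <- if (ck$tau <= 0) 1 else 1 - exp(-t / ck$tau)
      cut <- ck$k_dsb * D * y[1]
      K <- ck$k_pr + ck$k_in + ck$k_ld + ck$k_ti
      list(c(-cut + ck$k_pr * y[2], cut - K * y[2], ck$k_in * y[2],
             ck$k_ld * y[2], ck$k_ti * y[2]))
    }
    ref <- deSolve::lsoda(c(100, 0, 0, 0, 0), seq(0, 24, by = 3), rhs,
                          parms = NULL, rtol = 1e-10, atol = 1e-10)
    tr <- simulate_model(ck, t_grid = seq(0, 24, by = 3))
    expect_equal(tr$WT, unname(ref[, 2]), tolerance = 1e-7)
    expect_equal(tr$DSB, unname(ref[, 3]), tolerance = 1e-7)
    expect_equal(tr$IN, unname(ref[, 4]), tolerance = 1e-7)
  }
})

test_that("raising the precise-repair rate raises the late WT plateau", {
  base <- list(k_dsb = 0.63, tau = 0.5, k_in = 0.105, k_ld = 0.065)
  ends <- vapply(c(0.1, 0.3, 0.6, 1.2), function(kpr) {
    ck <- do.call(rate_coefficients, c(base, list(k_pr = kpr)))
    tr <- simulate_model(ck, t_grid = c(0, 24))
    tr$WT[2]
  }, numeric(1))
  expect_true(all(diff(ends) > 0))
  products <- vapply(c(0.1, 0.3, 0.6, 1.2), function(kpr) {
    ck <- do.call(rate_coefficients, c(base, list(k_pr = kpr)))
    tr <- simulate_model(ck, t_grid = c(0, 24))
    tr$IN[2] + tr$LD[2] + tr$TI[2]
  }, numeric(1))
  expect_true(all(diff(products) < 0))
})

test_that("derived statistics obey their algebraic identities", {
  ck <- kin_untreated()
  d <- derive_kinetics(ck)
  K <- resolution_rate(ck)
  expect_equal(d$half_life_resolution, log(2) / K, tolerance = 1e-12)
  expect_equal(d$half_life_generation, log(2) / 0.63, tolerance = 1e-12)
  # half-life of resolution at K = ln2 is exactly 1 h
  d2 <- derive_kinetics(rate_coefficients(k_dsb = 1, k_in = log(2)),
                        trajectory = simulate_model(
                          rate_coefficients(k_dsb = 1, k_in = log(2)),
                          seq(0, 4, 0.1)))
  expect_equal(d2$half_life_resolution, 1)
  # reciprocals of DSBs-per-product sum to one
  expect_equal(sum(1 / unlist(d$dsbs_per_product)), 1, tolerance = 1e-9)
  # per-hour likelihoods sum to one
  expect_equal(sum(unlist(d$likelihood)), 1, tolerance = 1e-9)
  # zero-rate channels are absent, never infinite
  expect_false("ti" %in% names(d$dsbs_per_product))
  # symmetric rates split everything three ways
  ck3 <- rate_coefficients(k_dsb = 1, k_pr = 0.2, k_in = 0.2, k_ld = 0.2)
  d3 <- derive_kinetics(ck3)
  expect_equal(unname(unlist(d3$dsbs_per_product)), rep(3, 3))
  lik <- unlist(d3$likelihood[c("precise", "indel", "large_del")])
  expect_equal(unname(lik / sum(lik)), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("event velocities and crossing times sit where the fluxes peak", {
  ck <- kin_untreated()
  tr <- simulate_model(ck, t_grid = seq(0, 24, by = 0.01))
  d <- derive_kinetics(ck, trajectory = tr)
  vdsb <- d$vmax[d$vmax$event == "dsb", ]
  # cleavage flux peaks early, while D(t) rises and WT is still high
  expect_lt(vdsb$t_vmax_h, 4)
  expect_gt(vdsb$vmax_percent_per_min, 0)
  # product fluxes peak with the DSB pool
  t_dsb_peak <- tr$t[which.max(tr$DSB)]
  vin <- d$vmax[d$vmax$event == "indel", ]
  expect_equal(vin$t_vmax_h, t_dsb_peak, tolerance = 0.02)
  # recurrent cutting pushes the cumulative counters past 100%
  expect_true(d$t_dsb_cum_100 < d$t_pr_cum_100)
  expect_lt(d$t_dsb_cum_100, 6.5)
  expect_gt(d$t_dsb_cum_100, 3)
})

test_that("recurrence cohorts never go negative and obey k_pr = 0 structure", {
  ck <- rate_coefficients(k_dsb = 0.63, tau = 0.5, k_pr = 0,
                          k_in = 0.105, k_ld = 0.065)
  rp <- recurrence_profile(ck, t_grid = seq(0, 24, by = 1), c_max = 4)
  # no precise repair: nothing is ever cut twice
  expect_true(all(as.matrix(rp$wt_cohorts[, -1]) < 1e-12))
  expect_true(all(as.matrix(rp$dsb_cohorts[, -1]) < 1e-12))
  expect_true(all(as.matrix(rp$wt_cohorts) >= -1e-12))
})

test_that("cohort sums reproduce the aggregate model exactly", {
  for (ck in random_coeffs(8, seed = 5)) {
    t_grid <- seq(0, 24, by = 2)
    tr <- simulate_model(ck, t_grid = t_grid, dt = 0.01)
    rp <- recurrence_profile(ck, t_grid = t_grid, c_max = 25, dt = 0.01)
    expect_lt(max(abs(rowSums(rp$wt_cohorts) - tr$WT)), 1e-6)
    expect_lt(max(abs(rowSums(rp$dsb_cohorts) - tr$DSB)), 1e-6)
    total <- rowSums(rp$wt_cohorts) + rowSums(rp$dsb_cohorts) + rp$IN +
      rp$LD + rp$TI
    expect_lt(max(abs(total - 100)), 1e-6)
  }
})

test_that("noiseless two-condition data are recovered to high accuracy", {
  obs <- kin_observed(noise_sd = 0)
  fit <- fit_kinetics(obs, n_boot = 0, n_starts = 4, seed = 11)
  truth <- c(0.63, 0.5, 0.554, 0.105, 0.065, 0.1, 0.005, 0.03)
  expect_lt(max(abs(fit$coef_table$estimate - truth) / truth), 0.01)
  expect_true(all(fit$r2 > 0.999))
})

test_that("fits are bit-identical under a fixed seed", {
  obs <- kin_observed(noise_sd = 2, seed = 21)
  f1 <- fit_kinetics(obs, n_boot = 20, n_starts = 2, seed = 5)
  f2 <- fit_kinetics(obs, n_boot = 20, n_starts = 2, seed = 5)
  expect_identical(f1$coef_table, f2$coef_table)
  expect_identical(f1$boot, f2$boot)
  expect_identical(f1$sse, f2$sse)
})

test_that("fit validation rejects malformed timeseries", {
  obs <- kin_observed(noise_sd = 0)
  expect_error(
    fit_kinetics(obs[obs$timepoint_h < 3, ], n_boot = 0, n_starts = 1),
    class = "lociq_config_error")
  bad <- obs
  bad$state[1] <- "XX"
  expect_error(fit_kinetics(bad, n_boot = 0, n_starts = 1),
               class = "lociq_input_error")
  flat <- obs
  flat$percent <- 25
  expect_warning(fit_kinetics(flat, n_boot = 0, n_starts = 1), "flat")
})

test_that("timeseries simulation is deterministic and noiseless at sd 0", {
  ck <- kin_untreated()
  a <- simulate_timeseries(ck, c(1, 2, 4), noise_sd = 2, seed = 3)
  b <- simulate_timeseries(ck, c(1, 2, 4), noise_sd = 2, seed = 3)
  expect_identical(a, b)
  clean <- simulate_timeseries(ck, c(1, 2, 4), noise_sd = 0, seed = 3)
  tr <- simulate_model(ck, t_grid = c(0, 1, 2, 4))
  for (tp in c(1, 2, 4)) {
    expect_equal(
      unique(clean$percent[clean$state == "WT" &
                             clean$timepoint_h == tp]),
      tr$WT[tr$t == tp], tolerance = 1e-12)
  }
})
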