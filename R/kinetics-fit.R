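#' Fit the cleavage/repair model jointly across conditions
#'
#' Estimates rate coefficients by bounded nonlinear least squares on the
#' observed state percentages, jointly across all conditions, states,
#' timepoints and replicates (unweighted, percent units). The cleavage
#' rate `k_dsb` and the trafficking delay `tau` are shared across
#' conditions — repair inhibitors change what happens *after* the cut,
#' not the nuclease — while each condition gets its own repair channel
#' rates. This contrast is what makes precise repair identifiable: the
#' observable WT state cannot distinguish never-cut from precisely
#' repaired loci, but the inhibited condition pins down the cleavage rate
#' and the untreated WT excess over it is precise repair.
#'
#' The optimiser works on log-scale parameters (L-BFGS-B within bounds),
#' from `n_starts` log-uniform starting points. Uncertainty comes from a
#' nonparametric bootstrap that resamples replicates with replacement
#' within each condition x timepoint x state cell (resampled deviations
#' scaled by `sqrt(n/(n-1))` to undo the small-sample variance shrinkage
#' of the within-cell bootstrap) and refits from the point estimate.
#' Everything is reproducible given `seed`.
#'
#' @param observed Tibble (or CSV path) with columns
#'   `condition, timepoint_h, replicate, state, percent`; states among
#'   `WT, DSB, IN, LD, TI`, percentages of genome copies, at least 5
#'   timepoints per condition.
#' @param n_boot Bootstrap refits (default 1000; 0 skips the bootstrap).
#' @param n_starts Multi-start count for the point fit (default 10).
#' @param seed Integer seed.
#' @param fit_ti Estimate a targeted-integration rate? Default: only if
#'   `TI` appears among the observed states.
#' @param shared Character vector of coefficients shared across
#'   conditions (default `c("k_dsb", "tau")`).
#' @param delay_form Passed to [rate_coefficients()].
#' @param weights `"none"` (default) or `"inverse_variance"` (weight each
#'   cell by 1/sd^2 of its replicates).
#' @param rate_bounds,tau_bounds Box constraints, h^-1 and h.
#' @param dt Integrator step during fitting (h, default 0.05).
#' @return A `kinetics_fit` object: `coefficients` (per-condition
#'   [rate_coefficients()]), `coef_table` (tidy tibble with bootstrap mean,
#'   sd and 95% percentile CI per coefficient), `r2` (per observed state),
#'   `sse`, `boot` (draws matrix), `observed`, `settings`.
#' @export
fit_kinetics <- function(observed, n_boot = 1000, n_starts = 10, seed = 1L,
                         fit_ti = NULL, shared = c("k_dsb", "tau"),
                         delay_form = c("exp", "logistic"),
                         weights = c("none", "inverse_variance"),
                         rate_bounds = c(1e-4, 10), tau_bounds = c(0.01, 5),
                         dt = 0.05) {
  delay_form <- match.arg(delay_form)
  weights <- match.arg(weights)
  if (is.character(observed)) observed <- read_timeseries_csv(observed)
  need <- c("condition", "timepoint_h", "replicate", "state", "percent")
  if (!all(need %in% names(observed))) {
    abort(paste0("observed timeseries must carry columns: ",
                 paste(need, collapse = ",")),
          class = "lociq_input_error")
  }
  bad_states <- setdiff(unique(observed$state), .kin_states)
  if (length(bad_states)) {
    abort(paste0("unknown observed state(s): ",
                 paste(bad_states, collapse = ", ")),
          class = "lociq_input_error")
  }
  if (!identical(sort(shared), sort(c("k_dsb", "tau")))) {
    abort("only k_dsb and tau can be shared across conditions",
          class = "lociq_config_error")
  }
  conditions <- unique(observed$condition)
  for (cond in conditions) {
    ntp <- length(unique(
      observed$timepoint_h[observed$condition == cond]))
    if (ntp < 5) {
      abort(paste0("condition '", cond, "' has ", ntp,
                   " timepoints; at least 5 are required"),
            class = "lociq_config_error")
    }
  }
  if (is.null(fit_ti)) fit_ti <- "TI" %in% observed$state
  if (sd(observed$percent) < 1e-9) {
    warn("observed data are flat; the fit will sit on a boundary")
  }

  delay_int <- if (delay_form == "logistic") 1L else 0L
  rates_per_cond <- c("k_pr", "k_in", "k_ld", if (fit_ti) "k_ti")
  par_names <- c("k_dsb", "tau",
                 unlist(lapply(conditions, function(cond)
                   paste(rates_per_cond, cond, sep = "@"))))
  npar <- length(par_names)
  lower <- log(c(rate_bounds[1], tau_bounds[1],
                 rep(rate_bounds[1], npar - 2)))
  upper <- log(c(rate_bounds[2], tau_bounds[2],
                 rep(rate_bounds[2], npar - 2)))

  # per-condition observation layout, fixed once
  layout <- lapply(conditions, function(cond) {
    d <- observed[observed$condition == cond, ]
    tp <- sort(unique(d$timepoint_h))
    w <- rep(1, nrow(d))
    if (weights == "inverse_variance") {
      sds <- dplyr::summarise(
        dplyr::group_by(d, .data$timepoint_h, .data$state),
        s = sd(.data$percent), .groups = "drop")
      key <- paste(d$timepoint_h, d$state)
      s <- sds$s[match(key, paste(sds$timepoint_h, sds$state))]
      s[!is.finite(s) | s < 1e-3] <- max(1e-3, median(s, na.rm = TRUE))
      w <- 1 / s^2
    }
    list(tp = tp, it = match(d$timepoint_h, tp),
         is = match(d$state, .kin_states), y = d$percent, w = w,
         cell = paste(d$timepoint_h, d$state))
  })
  names(layout) <- conditions

  cond_par_idx <- lapply(seq_along(conditions), function(ci) {
    idx <- 2L + (ci - 1L) * length(rates_per_cond) +
      seq_along(rates_per_cond)
    setNames(idx, rates_per_cond)
  })
  names(cond_par_idx) <- conditions

  objective <- function(theta, y_list) {
    p <- exp(theta)
    sse <- 0
    for (ci in seq_along(conditions)) {
      lay <- layout[[ci]]
      idx <- cond_par_idx[[ci]]
      k_ti <- if (fit_ti) p[idx[["k_ti"]]] else 0
      m <- .ode_simulate_cpp(lay$tp, 100, p[1], p[2], delay_int,
                             p[idx[["k_pr"]]], p[idx[["k_in"]]],
                             p[idx[["k_ld"]]], k_ti, dt)
      pred <- m[cbind(lay$it, lay$is)]
      r <- y_list[[ci]] - pred
      sse <- sse + sum(lay$w * r * r)
    }
    sse
  }

  y0 <- lapply(layout, function(l) l$y)
  run_fit <- function(theta0, y_list, factr = 1e4) {
    optim(theta0, objective, y_list = y_list, method = "L-BFGS-B",
          lower = lower, upper = upper,
          control = list(maxit = 300, factr = factr))
  }

  starts <- withr::with_seed(seed, {
    s <- matrix(runif(n_starts * npar, rep(lower, each = n_starts),
                      rep(upper, each = n_starts)),
                nrow = n_starts)
    # one deliberate mid-range start among the random ones
    s[1, ] <- log(c(0.5, 0.5, rep(0.1, npar - 2)))
    s
  })
  fits <- apply(starts, 1, run_fit, y_list = y0, simplify = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  theta_hat <- best$par
  p_hat <- setNames(exp(theta_hat), par_names)

  # per-state R^2, pooled over conditions
  r2 <- local({
    pred_all <- numeric(0); y_all <- numeric(0); st_all <- integer(0)
    p <- exp(theta_hat)
    for (ci in seq_along(conditions)) {
      lay <- layout[[ci]]
      idx <- cond_par_idx[[ci]]
      k_ti <- if (fit_ti) p[idx[["k_ti"]]] else 0
      m <- .ode_simulate_cpp(lay$tp, 100, p[1], p[2], delay_int,
                             p[idx[["k_pr"]]], p[idx[["k_in"]]],
                             p[idx[["k_ld"]]], k_ti, dt)
      pred_all <- c(pred_all, m[cbind(lay$it, lay$is)])
      y_all <- c(y_all, lay$y)
      st_all <- c(st_all, lay$is)
    }
    vapply(sort(unique(st_all)), function(s) {
      sel <- st_all == s
      1 - sum((y_all[sel] - pred_all[sel])^2) /
        sum((y_all[sel] - mean(y_all[sel]))^2)
    }, numeric(1)) |> setNames(.kin_states[sort(unique(st_all))])
  })

  boot <- NULL
  if (n_boot > 0) {
    # Replicate resampling with replacement within each condition x
    # timepoint x state cell. The naive n-out-of-n cell bootstrap
    # understates the sampling variance of a cell mean by (n-1)/n, so the
    # resampled deviations from the cell mean are scaled by
    # sqrt(n/(n-1)) — the usual small-sample unbiasedness correction.
    cells <- lapply(layout, function(lay) split(seq_along(lay$y), lay$cell))
    boot <- withr::with_seed(seed + 1L, {
      draws <- matrix(NA_real_, n_boot, npar,
                      dimnames = list(NULL, par_names))
      for (b in seq_len(n_boot)) {
        y_b <- lapply(seq_along(conditions), function(ci) {
          y <- layout[[ci]]$y
          out <- y
          for (members in cells[[ci]]) {
            m <- length(members)
            res <- y[sample(members, m, replace = TRUE)]
            if (m > 1) {
              mu <- mean(y[members])
              res <- mu + sqrt(m / (m - 1)) * (res - mu)
            }
            out[members] <- res
          }
          out
        })
        draws[b, ] <- exp(run_fit(theta_hat, y_b, factr = 1e7)$par)
      }
      draws
    })
  }

  coef_table <- tibble::tibble(
    term = sub("@.*$", "", par_names),
    condition = ifelse(grepl("@", par_names),
                       sub("^.*@", "", par_names), "shared"),
    estimate = unname(p_hat),
    boot_mean = if (is.null(boot)) NA_real_ else colMeans(boot),
    boot_sd = if (is.null(boot)) NA_real_ else apply(boot, 2, sd),
    ci_low = if (is.null(boot)) NA_real_ else
      apply(boot, 2, quantile, 0.025),
    ci_high = if (is.null(boot)) NA_real_ else
      apply(boot, 2, quantile, 0.975))

  coefficients <- lapply(conditions, function(cond) {
    idx <- cond_par_idx[[cond]]
    rate_coefficients(
      k_dsb = p_hat[["k_dsb"]], tau = p_hat[["tau"]],
      k_pr = p_hat[[idx[["k_pr"]]]], k_in = p_hat[[idx[["k_in"]]]],
      k_ld = p_hat[[idx[["k_ld"]]]],
      k_ti = if (fit_ti) p_hat[[idx[["k_ti"]]]] else 0,
      delay_form = delay_form)
  })
  names(coefficients) <- conditions

  structure(
    list(coefficients = coefficients, coef_table = coef_table, r2 = r2,
         sse = best$value, boot = boot, observed = observed,
         settings = list(n_boot = n_boot, n_starts = n_starts, seed = seed,
                         fit_ti = fit_ti, delay_form = delay_form,
                         weights = weights, dt = dt,
                         rate_bounds = rate_bounds,
                         tau_bounds = tau_bounds)),
    class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> %d condition(s), SSE %.4g\n",
              length(x$coefficients), x$sse))
  print(as.data.frame(x$coef_table), digits = 4, row.names = FALSE)
  cat("R^2 per state:",
      paste(sprintf("%s %.4f", names(x$r2), x$r2), collapse = ", "), "\n")
  invisible(x)
}

#' Fitted model trajectories for every condition of a fit
#'
#' @param fit A [fit_kinetics()] result.
#' @param t_grid Output times (h).
#' @return A tibble of trajectories with a `condition` column.
#' @export
fitted_trajectories <- function(fit, t_grid = seq(0, 24, by = 0.1)) {
  dplyr::bind_rows(lapply(names(fit$coefficients), function(cond) {
    tr <- simulate_model(fit$coefficients[[cond]], t_grid)
    tibble::tibble(condition = cond, tr)
  }))
}

#' Plot observed points and fitted curves
#'
#' @param fit A [fit_kinetics()] result.
#' @param t_grid Curve grid (h).
#' @return A ggplot object (requires ggplot2).
#' @export
plot_kinetics_fit <- function(fit, t_grid = seq(0, 24, by = 0.1)) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_kinetics_fit requires ggplot2")
  }
  curves <- tidyr::pivot_longer(fitted_trajectories(fit, t_grid),
                                dplyr::all_of(.kin_states),
                                names_to = "state", values_to = "percent")
  curves <- curves[curves$state %in% unique(fit$observed$state), ]
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$t, y = .data$percent,
                               colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = fit$observed,
      ggplot2::aes(x = .data$timepoint_h, y = .data$percent,
                   colour = .data$state), size = 1, alpha = 0.6) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "time post-editing (h)",
                  y = "percent of genome copies") +
    ggplot2::theme_minimal()
}

#' Read a kinetics timeseries CSV
#' (`condition,timepoint_h,replicate,state,percent`)
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_timeseries_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("condition", "timepoint_h", "replicate", "state", "percent")
  if (!all(need %in% names(df))) {
    abort(paste0("timeseries CSV must carry columns: ",
                 paste(need, collapse = ",")),
          class = "lociq_input_error")
  }
  df
}
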