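test_that("droplet tallies enforce their class-sum and sign invariants", {
  expect_s3_class(droplet_counts(100, 10, 20, 30, 40), "droplet_counts")
  expect_error(droplet_counts(100, 10, 20, 30, 50),
               class = "lociq_input_error")
  expect_error(droplet_counts(100, -1, 21, 30, 50),
               class = "lociq_input_error")
  expect_error(droplet_counts(0, 0, 0, 0, 0), class = "lociq_input_error")
})

test_that("droplet CSV round-trips bit-exactly and validates per row", {
  df <- simulate_sample_wells(mixture_truth(), default_panel(),
                              sample_id = "s1", n_droplets = 2000,
                              seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_droplet_csv(df, path)
  expect_identical(names(read_droplet_csv(path)),
                   c("well_id", "sample_id", "assay_id", "n_total",
                     "n_double", "n_fam_only", "n_hex_only", "n_negative"))
  expect_equal(as.data.frame(read_droplet_csv(path)), as.data.frame(df))
  bad <- df
  bad$n_double[3] <- bad$n_double[3] + 1
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path2)
  expect_error(read_droplet_csv(path2), "row 3",
               class = "lociq_input_error")
})

test_that("the Poisson estimator matches its closed form and error cases", {
  expect_identical(estimate_lambda(20000, 20000), 0)
  expect_equal(estimate_lambda(10000, 20000), log(2))
  expect_error(estimate_lambda(0, 20000),
               class = "lociq_saturation_error")
  expect_error(estimate_lambda(30000, 20000),
               class = "lociq_input_error")
})

test_that("lambda decreases strictly as negatives increase at fixed total", {
  negs <- seq(100, 20000, by = 700)
  lams <- vapply(negs, estimate_lambda, numeric(1), n_total = 20000)
  expect_true(all(diff(lams) < 0))
})

test_that("the estimator is unbiased on simulated wells and bias shrinks with droplet count", {
  # Monte-Carlo oracle: direct Poisson loading at true lambda = 0.5
  est_at <- function(n_total, n_seeds, lambda = 0.5) {
    mean(vapply(seq_len(n_seeds), function(s) {
      n_neg <- withr::with_seed(s, sum(rpois(n_total, lambda) == 0))
      estimate_lambda(n_neg, n_total)
    }, numeric(1)))
  }
  expect_lt(abs(est_at(20000, 200) - 0.5), 0.01)
  # consistency: absolute bias shrinks as n_total grows
  bias <- vapply(c(1e3, 1e4, 1e5), function(n) {
    abs(est_at(n, 60) - 0.5)
  }, numeric(1))
  expect_lt(bias[3], 0.004)
  expect_lt(bias[3], bias[1] + 0.004)
})

test_that("linkage is zero at independence and inverts exactly on expected counts", {
  w <- droplet_counts(10000, 2500, 2500, 2500, 2500)
  expect_identical(estimate_linkage(w)$lambda_link, 0)
  # fully linked population at lambda_link = 0.3
  p <- exp(-0.3)
  w2 <- droplet_counts(10000, (1 - p) * 10000, 0, 0, p * 10000)
  expect_equal(estimate_linkage(w2)$lambda_link, 0.3, tolerance = 1e-12)
  expect_equal(estimate_linkage(w2)$linked_fraction, 1, tolerance = 1e-12)
})

test_that("the closed-form linkage estimator is exact on a concentration grid", {
  grid <- expand.grid(lf = c(0, 0.2, 0.5, 1), lh = c(0, 0.3, 0.8),
                      ll = c(0, 0.1, 0.4, 1.2))
  for (i in seq_len(nrow(grid))) {
    w <- well_from_lambdas(grid$ll[i], grid$lf[i], grid$lh[i])
    est <- estimate_linkage(w)
    expect_lt(abs(est$lambda_link - grid$ll[i]), 1e-10)
    expect_lt(abs(est$lambda_fam_free - grid$lf[i]), 1e-10)
    expect_lt(abs(est$lambda_hex_free - grid$lh[i]), 1e-10)
  }
})

test_that("linkage recovery on simulated droplets is unbiased", {
  # free FAM 0.4, free HEX 0.5, linked 0.2 in 50k droplets
  p <- lociq:::.droplet_class_probs(0.2, 0.4, 0.5)
  ests <- vapply(1:200, function(s) {
    counts <- withr::with_seed(s, as.numeric(rmultinom(1, 50000, p)))
    w <- droplet_counts(50000, counts[1], counts[2], counts[3], counts[4])
    estimate_linkage(w)$lambda_link
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.2), 0.01)
})

test_that("negative linkage estimates floor at zero but keep the raw value", {
  # independence with sampling jitter towards fewer double positives
  w <- droplet_counts(10000, 2400, 2600, 2600, 2400)
  est <- estimate_linkage(w)
  expect_identical(est$lambda_link, 0)
  expect_lt(est$raw[["lambda_link"]], 0)
})

test_that("copy CIs are deterministic, degenerate on blank wells, and well calibrated", {
  w <- droplet_counts(20000, 1000, 2000, 3000, 14000)
  c1 <- copies_with_ci(w, n_boot = 200, seed = 9)
  c2 <- copies_with_ci(w, n_boot = 200, seed = 9)
  expect_identical(c1, c2)
  expect_equal(c1$copies_fam, c1$lambda_fam * 20000)
  expect_true(c1$ci_fam[["low"]] <= c1$lambda_fam &&
                c1$lambda_fam <= c1$ci_fam[["high"]])

  blank <- droplet_counts(20000, 0, 0, 0, 20000)
  cb <- copies_with_ci(blank, n_boot = 100, seed = 1)
  expect_identical(cb$copies_fam, 0)
  expect_lt(cb$ci_fam[["high"]], 1e-9)

  # coverage at true lambda 0.3: at least 93% of 95% CIs contain truth
  n_negs <- withr::with_seed(1, rbinom(500, 20000, exp(-0.3)))
  hits <- vapply(seq_along(n_negs), function(i) {
    w <- droplet_counts(20000, 0, 20000 - n_negs[i], 0, n_negs[i])
    ci <- copies_with_ci(w, n_boot = 1000, seed = i)$ci_fam
    ci[["low"]] <= 0.3 && 0.3 <= ci[["high"]]
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})
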