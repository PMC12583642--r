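test_that("double normalisation matches its closed form and identities", {
  expect_equal(double_normalise(4000, c(8000, 8000), 9000,
                                c(9000, 9000))$value, 0.5)
  # mock against itself
  expect_equal(double_normalise(9000, c(9000, 9000), 9000,
                                c(9000, 9000))$value, 1)
  expect_error(double_normalise(4000, c(8000), 0, c(9000)),
               class = "lociq_input_error")
  expect_error(double_normalise(4000, numeric(0), 9000, c(9000)),
               class = "lociq_input_error")
  expect_error(double_normalise(-1, c(8000), 9000, c(9000)),
               class = "lociq_input_error")
})

test_that("double normalisation is invariant to rescaling a sample's copies", {
  base <- double_normalise(3000, c(8000, 7500), 9000, c(9100, 8900))$value
  scaled <- double_normalise(3000 * 3.7, c(8000, 7500) * 3.7, 9000,
                             c(9100, 8900))$value
  expect_equal(scaled, base, tolerance = 1e-12)
})

# expected-count wells for a given truth across the default panel
expected_wells <- function(truth, panel = default_panel()) {
  lapply(stats::setNames(panel$assays$id, panel$assays$id), function(id) {
    role <- panel$assays$role[panel$assays$id == id]
    simulate_droplet_well(truth, role, expected = TRUE, assay_id = id)
  })
}

test_that("edge arithmetic follows the stated rule", {
  # f_FAM 0.30, f_HEX 0.80 built from expected counts
  mk <- function(fam_frac, hex_frac) {
    # locus copies scaled so mock lambda is 0.8
    well_from_lambdas(0.8 * fam_frac, 0, 0.8 * (hex_frac - fam_frac),
                      n_total = 1e5, assay_id = "edge1")
  }
  ref <- well_from_lambdas(0.8, 0, 0, n_total = 1e5, assay_id = "ref1")
  out <- edge_summary(mk(0.30, 0.80), list(ref), mk(1, 1), list(ref))
  expect_equal(out$percent[out$state == "wt"], 30, tolerance = 1e-9)
  expect_equal(out$percent[out$state == "indel"], 50, tolerance = 1e-9)
  expect_equal(out$percent[out$state == "other"], 20, tolerance = 1e-9)
})

test_that("mock self-normalisation yields exactly wt 100 and zero aberrations", {
  wells <- expected_wells(mock_truth())
  edge <- edge_summary(wells$edge1, wells[c("ref1", "ref2")],
                       wells$edge1, wells[c("ref1", "ref2")])
  expect_equal(edge$percent[edge$state == "wt"], 100, tolerance = 1e-9)
  expect_equal(edge$percent[edge$state == "indel"], 0, tolerance = 1e-9)
  expect_equal(edge$percent[edge$state == "other"], 0, tolerance = 1e-9)
  flank <- flanking_summary(wells$flank1, wells[c("ref1", "ref2")],
                            wells$flank1, wells[c("ref1", "ref2")])
  expect_equal(flank$percent[flank$state == "dsb"], 0, tolerance = 1e-9)
  expect_equal(flank$percent[flank$state == "linked"], 100,
               tolerance = 1e-9)
  expect_equal(flank$percent[flank$state == "trim5"], 0, tolerance = 1e-9)
})

test_that("flanking arithmetic follows the stated rule for both statistics", {
  mk <- function(f5, f3, fl) {
    well_from_lambdas(0.8 * fl, 0.8 * (f5 - fl), 0.8 * (f3 - fl),
                      n_total = 1e5, assay_id = "flank1")
  }
  ref <- well_from_lambdas(0.8, 0, 0, n_total = 1e5, assay_id = "ref1")
  out <- flanking_summary(mk(0.90, 0.85, 0.60), list(ref), mk(1, 1, 1),
                          list(ref), dsb_statistic = "mean")
  expect_equal(out$percent[out$state == "trim5"], 10, tolerance = 1e-8)
  expect_equal(out$percent[out$state == "trim3"], 15, tolerance = 1e-8)
  expect_equal(out$percent[out$state == "dsb"], 27.5, tolerance = 1e-8)
  out_min <- flanking_summary(mk(0.90, 0.85, 0.60), list(ref),
                              mk(1, 1, 1), list(ref),
                              dsb_statistic = "min")
  expect_equal(out_min$percent[out_min$state == "dsb"], 25,
               tolerance = 1e-8)
})

test_that("one-sided deletions plus DSBs are recovered without cross-talk", {
  truth <- locus_ground_truth(wt = 0.65, dsb = 0.25, large_del_5 = 0.10)
  wells <- expected_wells(truth)
  mockw <- expected_wells(mock_truth())
  out <- flanking_summary(wells$flank1, wells[c("ref1", "ref2")],
                          mockw$flank1, mockw[c("ref1", "ref2")])
  expect_equal(out$percent[out$state == "dsb"], 25, tolerance = 1e-6)
  expect_equal(out$percent[out$state == "trim5"], 10, tolerance = 1e-6)
  expect_equal(out$percent[out$state == "trim3"], 0, tolerance = 1e-6)
})

test_that("aneuploidy changes are signed percent deviations from the mock", {
  truth <- locus_ground_truth(wt = 1, aneu_p_change = -0.10,
                              aneu_q_change = 0.05)
  panel <- default_panel(with_aneu = TRUE)
  wells <- expected_wells(truth, panel)
  mockw <- expected_wells(mock_truth(), panel)
  out <- aneuploidy_summary(wells$aneu1, wells[c("ref1", "ref2")],
                            mockw$aneu1, mockw[c("ref1", "ref2")])
  expect_equal(out$percent[out$state == "aneu_p_change"], -10,
               tolerance = 1e-6)
  expect_equal(out$percent[out$state == "aneu_q_change"], 5,
               tolerance = 1e-6)
})

test_that("targeted integration, VCN and episomal pool follow the copy ratios", {
  # junction 530 copies per 1000 locus copies -> TI 53%
  ref <- well_from_lambdas(0.5, 0, 0, n_total = 1e5, assay_id = "ref1")
  ti <- well_from_lambdas(0, 0.5 * 0.53, 0, n_total = 1e5,
                          assay_id = "ti1")
  donor <- well_from_lambdas(0, 0.5 * 0.53, 0, n_total = 1e5,
                             assay_id = "donor1")
  out <- ti_summary(ti, donor, list(ref), ploidy = 2)
  expect_equal(out$percent[out$state == "targeted_integration"], 53,
               tolerance = 1e-6)
  expect_equal(attr(out, "vcn"), 2 * 0.53, tolerance = 1e-6)
  # identical digested and undigested VCN -> concatemer ratio 1
  out2 <- ti_summary(ti, donor, list(ref), digested_donor_well = donor)
  expect_equal(attr(out2, "concatemer_ratio"), 1, tolerance = 1e-9)
})

test_that("a large episomal pool dominates the donor copies", {
  truth <- locus_ground_truth(wt = 0.5, ti = 0.384,
                              episome_copies_per_cell = 150)
  panel <- default_panel(with_donor = TRUE)
  wells <- expected_wells(truth, panel)
  out <- ti_summary(wells$ti1, wells$donor1, wells[c("ref1", "ref2")])
  expect_equal(out$percent[out$state == "targeted_integration"], 38.4,
               tolerance = 1e-4)
  expect_gt(out$percent[out$state == "episomal_fraction"], 99)
})

test_that("combine stacks disjoint states, resolves overlap and flags bad totals", {
  edge <- tibble::tibble(state = c("wt", "indel", "other"),
                         percent = c(15, 40, 45), sd = NA_real_)
  flank <- tibble::tibble(state = c("trim5", "trim3", "dsb", "linked"),
                          percent = c(10, 0, 25, 55), sd = NA_real_)
  s <- combine_summary(edge, flank, flank_distance_bp = 50)
  st <- setNames(s$states$percent, s$states$state)
  expect_equal(unname(st[c("wt", "indel", "large_del", "dsb", "other",
                           "ti")]), c(15, 40, 10, 25, 10, 0))
  expect_equal(s$total, 100)
  expect_false(s$flag)
  expect_false(s$clamped)
  # mock: everything in wt
  s_mock <- combine_summary(
    tibble::tibble(state = c("wt", "indel", "other"),
                   percent = c(100, 0, 0), sd = NA_real_),
    tibble::tibble(state = c("trim5", "trim3", "dsb", "linked"),
                   percent = c(0, 0, 0, 100), sd = NA_real_))
  expect_equal(s_mock$total, 100)
  expect_equal(s_mock$states$percent[s_mock$states$state == "wt"], 100)
  # overlap clamping is recorded
  s_cl <- combine_summary(
    tibble::tibble(state = c("wt", "indel", "other"),
                   percent = c(15, 40, 20), sd = NA_real_), flank)
  expect_true(s_cl$clamped)
  expect_equal(s_cl$states$percent[s_cl$states$state == "other"], 0)
  # totals far from 100 raise the flag
  s_bad <- combine_summary(
    tibble::tibble(state = c("wt", "indel", "other"),
                   percent = c(15, 40, 10), sd = NA_real_),
    tibble::tibble(state = c("trim5", "trim3", "dsb", "linked"),
                   percent = c(5, 0, 10, 80), sd = NA_real_))
  expect_true(s_bad$flag)
  # short flank distances report trimming, not large deletions
  s_trim <- combine_summary(edge, flank, flank_distance_bp = 20)
  expect_equal(s_trim$states$percent[s_trim$states$state == "large_del"], 0)
  expect_equal(s_trim$trim5, 10)
})

test_that("expected-count mixtures conserve a total of exactly 100", {
  mixes <- list(
    mixture_truth(),
    locus_ground_truth(wt = 0.5, indel = 0.3, dsb = 0.2),
    locus_ground_truth(wt = 0.25, indel = 0.25, large_del_3 = 0.2,
                       dsb = 0.2, other_loss = 0.1))
  panel <- default_panel()
  for (truth in mixes) {
    droplets <- dplyr::bind_rows(
      simulate_sample_wells(mock_truth(), panel, "mock", n_wells = 1,
                            expected = TRUE),
      simulate_sample_wells(truth, panel, "edited", n_wells = 1,
                            expected = TRUE))
    res <- quantify(droplets, panel)
    tot <- sum(res$percent[res$sample_id == "edited" &
                             res$state %in% c("wt", "indel", "large_del",
                                              "dsb", "other", "ti")])
    expect_equal(tot, 100, tolerance = 1e-6)
  }
})

test_that("quantify validates panel/droplet consistency", {
  panel <- default_panel()
  droplets <- simulate_sample_wells(mock_truth(), panel, "mock",
                                    n_droplets = 2000, seed = 1)
  droplets$assay_id[1] <- "mystery"
  expect_error(quantify(droplets, panel), class = "lociq_config_error")
  expect_error(
    assay_panel(
      assays = list(list(id = "edge1", role = "edge")),
      samples = list(list(id = "mock", condition = "mock",
                          timepoint_h = 0)),
      mock_sample = "mock"),
    class = "lociq_config_error")
})
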