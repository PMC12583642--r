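# lociq

Absolute quantification of genome-integrity states at a nuclease-edited
locus from droplet digital PCR (dPCR) partition counts, and ODE
modelling of the cleavage/repair kinetics behind them.

Gene-editing readouts that amplify across the cut site (amplicon
sequencing, Sanger deconvolution, enzyme mismatch assays) only see
alleles that still amplify, so large deletions, unresolved double-strand
breaks (DSBs) and other structural lesions silently inflate the
remaining classes. dPCR counts molecules absolutely: the fraction of
negative droplets estimates `exp(-lambda)` for each channel, and the
excess of double-positive droplets over the rate expected by chance
measures whether two probed sequences still sit on one DNA molecule.
`lociq` turns a panel of such assays — edge (cut-site), flanking
(5′/3′ + linkage), aneuploidy, targeted-integration/episomal and
reference assays — into a stacked summary of

> % wildtype, % indel, % large deletion, % unresolved DSB,
> % other aberration, % targeted integration

per sample, via a double normalisation (reference assays, then a
mock-edited control) that makes every class an absolute fraction of
genome copies. On top of that it implements limit-of-blank /
limit-of-detection statistics for dilution series, and a three-state
kinetics model

```
dWT/dt  = −k_dsb·D(t)·WT + k_pr·DSB
dDSB/dt =  k_dsb·D(t)·WT − K·DSB        K = k_pr + k_in + k_ld + k_ti
dIN/dt  =  k_in·DSB    dLD/dt = k_ld·DSB    dTI/dt = k_ti·DSB
```

fitted jointly across untreated and repair-inhibited conditions
(shared `k_dsb` and trafficking delay `tau`, per-condition repair
rates) with bootstrap confidence intervals. The inhibitor contrast is
what makes *precise (error-free) repair* — invisible to any sequencing
readout — identifiable, and the model's cumulative counters and
recurrence cohorts quantify repeated cutting of precisely repaired
loci. A synthetic-data generator produces droplet wells, dilution
series and timeseries with known ground truth, so the whole pipeline is
testable without instrument data.

## Worked example

Simulate an edited sample with a known mixture (15% wildtype, 40%
indel, 10% large deletion, 25% DSB, 10% other), quantify it against its
mock control, and inspect the recovery:

```r
library(lociq)

panel <- default_panel()
truth <- locus_ground_truth(wt = 0.15, indel = 0.40, large_del_5 = 0.10,
                            dsb = 0.25, other_loss = 0.10)
droplets <- rbind(
  simulate_sample_wells(locus_ground_truth(wt = 1), panel, "mock", seed = 11),
  simulate_sample_wells(truth, panel, "edited", seed = 12))
res <- quantify(droplets, panel)
subset(as.data.frame(res), sample_id == "edited")
#>   sample_id condition timepoint_h     state percent    sd  flag
#>      edited       RNP          72        wt   15.24 0.163 FALSE
#>      edited       RNP          72     indel   40.47 0.719 FALSE
#>      edited       RNP          72 large_del   10.81 3.264 FALSE
#>      edited       RNP          72       dsb   24.88 1.166 FALSE
#>      edited       RNP          72     other    8.60    NA FALSE
#>      edited       RNP          72        ti    0.00    NA FALSE
#>      edited       RNP          72     trim5   10.81    NA FALSE
#>      edited       RNP          72     trim3    1.66    NA FALSE
```

Each state lands within sampling error of its ground truth (mean ± sd
over three replicate wells of 20 000 droplets); `flag` would mark any
sample whose state total leaves [90, 110]%.

Kinetics: simulate a two-condition timecourse, fit it, and derive the
headline statistics:

```r
tp <- c(1/12, 0.25, 0.5, 1, 2, 4, 6, 8, 12, 16, 20, 24)
untr <- rate_coefficients(k_dsb = 0.63, tau = 0.5, k_pr = 0.554,
                          k_in = 0.105, k_ld = 0.065)
inh  <- rate_coefficients(k_dsb = 0.63, tau = 0.5, k_pr = 0.100,
                          k_in = 0.005, k_ld = 0.030)
obs <- rbind(
  simulate_timeseries(untr, tp, noise_sd = 2, seed = 1, condition = "untreated"),
  simulate_timeseries(inh,  tp, noise_sd = 2, seed = 2, condition = "inhibited"))
fit <- fit_kinetics(obs, n_boot = 200, seed = 3)

d <- derive_kinetics(fit$coefficients$untreated)
unlist(d$dsbs_per_product)
#>   precise     indel large_del
#>  1.306859  6.895238 11.138462
d$half_life_resolution
#> [1] 0.9573856
```

Read: in the untreated condition a DSB resolves with half-life ~0.96 h,
and on average a locus is cut ~1.3 times per precise repair, ~6.9 times
per indel and ~11.1 times per large deletion — the reciprocals of these
sum to 1, since every resolved break ends in exactly one product.
`recurrence_profile(untr)` splits the population by how often each
locus has been cut (under these coefficients the uncleaved pool falls
below 1% by 12 h and more than five cleavage cycles are populated by
24 h), and `plot_kinetics_fit(fit)` overlays the fitted curves on the
observed points.

File-based entry points (`run_simulate()`, `run_quantify()`,
`run_kinetics()`, `run_lod()`) read and write the documented CSV/YAML/
JSON dialects; `inst/scripts/lociq.R` wraps them as a command-line tool
with `simulate`, `quantify`, `lod` and `fit` subcommands.

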