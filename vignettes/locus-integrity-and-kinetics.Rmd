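---
title: "Absolute locus integrity and cut-and-repair kinetics from droplet dPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute locus integrity and cut-and-repair kinetics from droplet dPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement problem

A nuclease-edited locus ends up in a heterogeneous mixture of states:
unchanged wildtype sequence, small indels, large deletions, unresolved
double-strand breaks (DSBs), integrated donor templates, and other
structural lesions. Methods that amplify across the cut site
(amplicon sequencing, Sanger deconvolution, T7E1) only see alleles that
still amplify, so every state that destroys the amplicon is silently
dropped and the remaining states are inflated. Droplet digital PCR
(dPCR) escapes this bias because it counts molecules absolutely:
partitioning the reaction into ~10^4--10^5 droplets makes the fraction
of *negative* droplets a direct estimate of `exp(-lambda)` for a
channel's mean occupancy `lambda`, whatever happened to the other
alleles.

`lociq` implements the full analysis chain for a panel of two-colour
assays read on such an instrument:

* **Edge assay** — one amplicon across the cut site, a FAM probe on the
  cleavage position and a HEX probe ~25 bp away. FAM counts wildtype,
  HEX counts wildtype + indels, total copy loss counts everything that
  destroyed the amplicon.
* **Flanking assay** — one amplicon on each side of the cut, read in a
  single well (FAM = 5′, HEX = 3′). Copy loss on a side is end
  trimming / large deletion in that direction; loss of *linkage*
  between the sides — excess double-positive droplets over the rate
  expected by chance — is an unresolved DSB.
* **Aneuploidy assay** — sub-telomeric p/q-arm copy numbers, reported
  as signed percent change.
* **Targeted-integration / episomal assay** — a locus–donor junction
  amplicon counts integrated copies; an amplicon internal to the donor
  counts all copies, so the difference is the episomal pool. A
  single-cut digested replicate of the donor-total assay exposes
  concatemers as a VCN ratio above 1.
* **Reference assays** — probe pairs on non-targeted chromosomes at the
  same inter-amplicon spacing, the denominator for everything.

### Poisson and linkage estimators

For each channel, `estimate_lambda()` inverts the negative fraction:
`lambda = ln(n_total / n_negative_in_channel)`. For linkage,
`estimate_linkage()` uses the three negative fractions of a dual-probe
well; under independent Poisson loading of free-FAM, free-HEX and
linked molecules,

```
lambda_link = ln f_neg − ln f_FAMneg − ln f_HEXneg
```

which is exact on expected fractions (the package tests this to 1e-10
on a concentration grid). Sampling noise can push `lambda_link` or the
free-molecule remainders slightly negative; because concentrations are
physical non-negatives they are floored at zero, and the raw values are
kept in the returned object for diagnostics. Confidence intervals come
from a multinomial bootstrap over the four droplet classes
(`copies_with_ci()`, percentile intervals, 1000 resamples by default);
the packaged coverage check verifies that at the occupancies these
assays run at, at least 93% of nominal-95% intervals contain the truth.

All quantities stay on the per-droplet `lambda` scale with
`copies = lambda * n_total`; a copies-per-microlitre conversion with a
configurable 0.85 nL partition volume is provided for reporting only,
because every downstream statistic is a ratio of copies and therefore
volume-invariant.

### Double normalisation

Each mutation assay is first normalised by the averaged reference-assay
copies of the same sample (cancelling gDNA dose), then by the same
ratio formed in a mock-edited control (cancelling per-assay
amplification efficiency). The result is a fraction of loci on a scale
where unedited is exactly 1; multiplying all copies of a sample by any
constant leaves it unchanged. Donor-specific assays are the one
exception: the mock carries no donor, so they are normalised against
the reference copies only.

### Combining assays into one stacked summary

The edge assay's total copy loss contains the unresolved DSBs, large
deletions, and integrated donors that other assays resolve explicitly,
so `combine_summary()` subtracts those and reports the clamped
remainder as "other aberrations" (translocations, inversions, complex
lesions); clamping events are recorded. Flanking copy loss is labelled
by the assay's primer/probe distance from the cut: beyond the
configurable 25 bp threshold it stacks as a large deletion, and the
per-side trims are reported in either case. The state total should be
100; totals outside [90, 110] raise a flag rather than an error,
because accumulated normalisation error and genuine biology (donor
duplications, unusual rearrangements) can both push it out.

**Choice of the DSB statistic.** The linked fraction must be compared
with the fraction of loci that still carry *both* flanks. We default to
`min(f5, f3) − f_link`. The symmetric alternative `mean(f5, f3) −
f_link` is available (`dsb_statistic = "mean"`), but it is confounded
by one-sided deletions: a locus that lost its 5′ flank still
contributes a free 3′ flank, so the mean of the sides exceeds the
both-flanks fraction by half the one-sided deletion load and the DSB
estimate inflates accordingly. `min` is exact for one-sided loss and
identical to `mean` under symmetric loss; with the package's
synthetic generator (one-sided deletions) only `min` recovers the truth,
which decided the default.

## The synthetic-data generator

`simulate_droplet_well()` converts a declared ground truth — fractions
of wildtype, indel, 5′/3′ large deletion, unresolved DSB, local
rearrangement ("other"), and integrated donor, plus episome copies,
arm-level aneuploidy, ploidy and cells assayed — into the molecule
species each assay sees (linked pairs, free single-channel molecules),
and draws the four-class droplet tally from the exact Poisson
co-occupancy law. This is distributionally identical to placing
molecules into droplets one at a time. Defaults are 20 000 droplets per
well and three replicate wells per assay, with a 2% lognormal per-well
dose jitter emulating pipetting variability; `expected = TRUE` returns
real-valued expected counts, the noiseless limit used by the exactness
tests. An optional per-molecule shear probability (default 0) emulates
random gDNA fragmentation between linked probes.

The molecular reading of the "other" class deserves a note: it is
modelled as a lesion confined between the flanking amplicons (local
insertion, inversion, complex rearrangement) — it destroys the cut-site
amplicon but leaves both flanks present and linked. Large deletions, by
contrast, span the cut site beyond a flank. These are the assumptions
under which the subtraction scheme of `combine_summary()` is exact; real
translocations that relocate one flank elsewhere in the genome would
appear partly as DSB-like linkage loss, which is one reason the "other"
class of real data is a lower bound.

What the generator deliberately does not emulate: fluorescence
amplitudes, rain, threshold ambiguity (inputs are post-threshold
tallies), PCR efficiency differences between assays beyond what the
mock normalisation cancels, and donor homology arms long enough to make
the flanking assay blind (`flanking_valid = FALSE` suppresses flanking
outputs for such designs). Passing round-trip tests therefore
demonstrates correctness of the estimator chain, not robustness to
thresholding artefacts.

## Detection limits

`limit_of_blank()` is the one-sided 95% construction
`LoB = mean + 1.645 sd` over replicate blank measurements (sample sd,
n−1 denominator), and `limit_of_detection()` adds `1.645 sd` of the
lowest dilution level whose mean exceeds the LoB, alongside the
slope/intercept/R² of observed against expected fractions.
Dilution-factor-corrected values are expected as input; the
`dilution_series` container keeps expected and observed side by side.

One calibration subtlety: the plug-in construction is asymptotically a
5% exceedance bound, and the package's calibration check uses
50-replicate blank batches, where the simulated exceedance sits within
a point of the nominal 5%. With
small blank sets the bound is slightly anticonservative — for 20
replicates the exact rate is `P(t_19 > 1.645/sqrt(1 + 1/20)) = 6.2%` —
and the test suite asserts that finite-sample value too, so users of
small blank panels know what the bound actually delivers.

## The cleavage/repair kinetics model

The three-state model tracks intact loci (WT), unresolved breaks (DSB)
and resolved products, with the products split into indel (IN), large
deletion (LD) and targeted integration (TI):

```
dWT/dt  = −k_dsb · D(t) · WT + k_pr · DSB
dDSB/dt =  k_dsb · D(t) · WT − K · DSB,   K = k_pr + k_in + k_ld + k_ti
dIN/dt  =  k_in · DSB      dLD/dt = k_ld · DSB      dTI/dt = k_ti · DSB
```

plus cumulative counters for cleavage events and precise repairs, which
are unbounded above 100% — the signature of recurrent cutting.
`D(t)` models nuclear trafficking of the electroporated RNP; the
default is the saturating exponential `1 − exp(−t/tau)` (smooth,
monotone, single parameter, `D(0) = 0`, `D(∞) = 1`), with a logistic
alternative behind `delay_form = "logistic"` for sensitivity analyses.
All rates are first-order, per hour.

**Identifiability.** Precisely repaired loci are experimentally
indistinguishable from never-cut loci, so the observable WT state maps
to the model's WT compartment. The trick that makes `k_pr`
identifiable is the repair-inhibitor contrast: `k_dsb` and `tau` are
shared between the untreated and inhibited conditions (the inhibitors
act downstream of cleavage), while all four repair rates are
per-condition — the observed difference in WT decay between conditions
is then attributable to precise repair. Fits use the first 24 h,
before inhibitor washout changes the repair dynamics.

**Fitting.** `fit_kinetics()` minimises unweighted squared residuals in
percent units across all conditions, states, timepoints and replicates
(inverse-variance weighting per replicate cell is available but not the
default, since there is no strong reason to trust three-replicate
variance estimates as weights). Optimisation is L-BFGS-B on log-scale
parameters within `[1e-4, 10] h^-1` (rates) and `[0.01, 5] h` (tau),
from 10 log-uniform multi-starts. Uncertainty comes from a bootstrap
that resamples replicates with replacement within each condition ×
timepoint × state cell and refits from the point estimate, 1000 draws
by default. Because an n-out-of-n bootstrap within a 3-replicate cell
understates the sampling variance of the cell mean by (n−1)/n, the
resampled deviations from the cell mean are scaled by `sqrt(n/(n−1))` —
without this correction the percentile intervals are systematically
narrow at three replicates. The packaged coverage study (50 noisy
datasets, 200 bootstrap draws each) verifies that the corrected 95%
intervals contain the true coefficients at least 90% of the time.

**Derived statistics.** From a coefficient set, `derive_kinetics()`
reports half-lives `ln2/k_dsb` (generation) and `ln2/K` (resolution),
computed from the coefficients with the delay window excluded (a
numerical generation half-life including `D(t)` is reported as a
diagnostic); cleavages-per-product `K/k_x`, whose reciprocals sum to 1
over the active channels, and which is reported as absent — not
infinite — for channels with zero rate; the per-hour fate of a DSB as
the exact one-hour transition probabilities `(k_x/K)(1 − exp(−K))`
with `exp(−K)` unresolved (a pure-ratio variant conditional on
resolution is available); peak event velocities in percent per minute
with their times; and the times at which cumulative cleavages and
precise repairs cross 100%.

**Recurrence cohorts.** `recurrence_profile()` expands the model by the
number of times each locus has been cut, applying the same rate
coefficients recursively to the shrinking pool of cleavable sequences:
`WT_c` (precisely repaired `c` times) feeds `DSB_{c+1}` on cleavage,
`DSB_c` feeds `WT_c` on precise repair. The terminal cohort recycles
into itself, which makes the cohort sums equal the aggregate model
exactly for any cohort cap — the package tests this identity to 1e-6 —
and a warning suggests a larger cap when the terminal cohort retains
mass above the reporting threshold (0.1% by default).

## Numerical choices

Integration is a fixed-step fourth-order Runge-Kutta scheme compiled in
C++ (step 0.001 h for simulation, 0.05 h inside the fitter). Two
properties motivated it over an adaptive solver: every Runge-Kutta
method preserves the linear conservation law `WT + DSB + IN + LD + TI`
exactly (round-off aside), whereas an adaptive solver only holds it to
its local tolerance; and the fitter needs ~10^4 solves per bootstrap
run, where a fixed small step on this non-stiff system is faster than
step-size control. At the default steps the trajectory error against a
reference adaptive integrator at `rtol = 1e-10` is below 1e-7 percent.

Other conventions: concentrations and normalised fractions are floored
at zero with raw values retained; `combine_summary()` clamps the
"other" class at zero and records the event; degenerate inputs
(saturated wells, empty reference lists, zero mock copies, fewer than
5 timepoints or 2 blanks) raise classed errors
(`lociq_input_error`, `lociq_config_error`, `lociq_saturation_error`,
`lociq_detection_failure`) rather than propagating NaN.

## Problem sizes used by the checks

The packaged checks run at desk scale: 20 000-droplet wells, three
replicates, 20-seed round trips for the droplet pipeline; 100 random
coefficient sets for conservation; 50 repetitions × 200 bootstrap
draws for CI coverage (12 timepoints from 5 minutes to 24 h, replicate
noise 2 points); 10 000 batches for LoB calibration. The timepoint grid
is deliberately early-heavy, because the trafficking delay `tau` is
only identified by observations inside its window.

## Known limitations

The model assumes time-constant first-order rates: no cell-cycle
dependence, no inhibitor washout within the fitted window, no per-cell
stochasticity (a locus-population ODE, not a single-cell model).
The assay layer cannot distinguish an episomal donor with long homology
arms from the locus (suppress flanking outputs in that design), custom
assays for specific MMEJ alleles, translocations or inversions are out
of scope, and classification of raw droplet amplitudes is upstream of
the package.
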