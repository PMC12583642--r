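Package: lociq
Title: Absolute Locus-Integrity Quantification and Cut-and-Repair Kinetics
    from Droplet Digital PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Absolute quantification of genome-integrity states at a
    nuclease-edited locus from droplet digital PCR (dPCR) partition counts.
    Converts per-well droplet classification tallies into molecule
    concentrations via Poisson partition statistics, estimates physical
    linkage between probed sequences from the excess of double-positive
    droplets, and combines edge, flanking, aneuploidy, targeted-integration
    and reference assays through a double normalisation (reference assays,
    then a mock-edited control) into absolute percentages of wildtype,
    indel, large-deletion, unresolved double-strand-break, other-aberration
    and targeted-integration loci. Includes limit-of-blank and
    limit-of-detection statistics for dilution series, a three-state
    ordinary-differential-equation model of nuclease cleavage and repair
    with joint fitting across repair-inhibited and untreated conditions,
    bootstrap confidence intervals, derived kinetic statistics (half-lives,
    event velocities, per-hour repair likelihoods, cleavages per repair
    product, recurrent-cleavage cohorts), and a synthetic-data generator
    for droplet wells, dilution series and kinetics timeseries with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
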