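Package: tractpm
Title: AT-Tract Binding Preference, Homologue Conservation and Tethered
    Particle Motion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy workflows for characterising minor-groove DNA recognition
    by nucleoid-associated proteins. Computes per-probe AT content and
    longest-AT-tract features from ChIP-microarray probe tables and
    summarises binding signal per feature bin; dereplicates homologue
    multiple sequence alignments, builds consensus sequences and scores
    per-column and per-residue conservation; quality-filters tethered
    particle motion (TPM) bead trajectories by scatter eccentricity,
    computes windowed root-mean-square motion and separates bound from
    unbound tether populations. Includes a Metropolis Monte-Carlo
    simulator of a surface-tethered worm-like-chain DNA-bead system and
    seeded generators of synthetic probe sets and alignments, so every
    analysis stage can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
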