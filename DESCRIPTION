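Package: phosbead
Title: Phosphatase Substrate Specificity from Encoded-Bead Assays and
    Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for multiplexed, spectrally encoded bead
    assays that profile Ser/Thr phosphatase specificity, together with the
    downstream phosphoproteomic and motif analyses. Covers spectral-code
    assignment and per-code aggregation with a synthesis-failure QC gate;
    dephosphorylation scoring and single-exponential kinetic fits;
    Langmuir-isotherm binding analysis with local and global (shared
    saturation) fitting, replicate aggregation and delta-delta-G ledgers
    relative to a reference peptide; regulated-phosphosite calling from
    TMT tables (Welch t-test with a fold-change gate), phosphatase
    specificity classes, label-free interactor calling with
    downshifted-normal imputation, and site-interactome joins; sequence
    context extraction, frequency and enrichment logos, and RVxF-class
    short-linear-motif scanning with additive delta-delta-G prediction.
    A synthetic-data generator with planted ground truth makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
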