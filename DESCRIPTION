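Package: connectograph
Title: Whole-Brain Resting-State Functional Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for edge-wise analysis of resting-state
    functional connectivity in clinical cohorts. From per-subject regional
    BOLD time series (or a labeled 4D image), the package performs nuisance
    regression and band-pass filtering, computes Fisher-z interregional
    correlation matrices on an atlas parcellation, identifies group-altered
    edges with a dual criterion (within-group one-sample t-tests with
    Bonferroni correction, between-group two-sample t-tests with
    Benjamini-Hochberg FDR correction), summarizes edge topology by lobe and
    hemisphere, and correlates altered-edge strengths with cognitive scores.
    A synthetic-cohort generator with ground-truth records supports
    validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    RNifti
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
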