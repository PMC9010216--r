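Package: fcmod
Title: Moderation Analysis of ROI-to-ROI Resting-State Functional
    Connectivity with Threshold-Free Network-Based Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether a grouping variable (such as chronic
    pain status) moderates the association between a continuous predictor
    (such as sleep quality) and resting-state functional connectivity.
    Implements per-edge second-level general linear models with an
    interaction term, Fisher-z connectivity computation from denoised ROI
    time series, hypothesis-restricted seed/target edge masks,
    Benjamini-Hochberg false-discovery-rate control, and threshold-free
    network-based statistics (TFNBS) with max-statistic permutation
    familywise error control. Includes a synthetic-data generator that
    emulates a small-cohort study design (covariates, planted interaction
    effects, correlated ROI time series) so that every stage of the
    pipeline can be validated without access to restricted subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
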