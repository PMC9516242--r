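Package: immunoCAD
Title: Peripheral Immune Profiling and Risk Models for Coronary
    Atherosclerosis
Version: 0.1.0
Authors@R:
    person("immunoCAD", "Developers", email = "immunocad@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for mass cytometry (CyTOF) immune
    profiling of peripheral blood in coronary atherosclerosis: event
    preprocessing (bead normalization, debris/dead-cell/doublet gating,
    arcsinh transformation), kNN-graph community clustering with
    marker-rule lineage annotation, per-sample immune feature tables,
    Gensini plaque-burden scoring, cohort statistics (chi-squared,
    summary-statistic one-way ANOVA, BH-adjusted t tests, correlation
    networks), and random-forest risk models with bootstrap class
    balancing, repeated-resampling stability feature selection, ROC and
    decision-curve evaluation. Ships a synthetic cohort generator so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    FNN,
    igraph,
    jsonlite,
    Rcpp,
    Rtsne,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
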