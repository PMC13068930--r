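Package: expobag
Title: Brain Age Gap Modelling and Exposome-Based Prediction of Grey-Matter Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for normative brain-age modelling and
    exposome-wide prediction of grey-matter health. Stage one trains brain-age
    regression models on parcellated grey-matter volumes from a healthy
    reference sample, applies a training-set age-bias correction, and computes
    the Brain Age Gap (BAG) as a per-participant indicator of grey-matter
    health. Stage two curates a table of exposome variables (uniqueness,
    aberrant and uninformative value exclusion, duration derivation,
    minimum-availability filtering), predicts BAG from the curated exposome
    under leakage-safe repeated nested cross-validation with training-fold
    confound residualization, assesses significance by permutation with
    Benjamini-Hochberg FDR across metrics, and explains predictions with
    Shapley additive attributions (exact path-dependent TreeSHAP for tree
    ensembles). A synthetic cohort generator with planted, exported ground
    truth (linear, nonlinear, duration, moderator and null exposure effects on
    an individual aging deviation) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    ranger,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
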