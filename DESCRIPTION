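Package: plasmarch
Title: Archetypal Stratification of Plasma Antibody Bead Array Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis pipeline for plasma profiles measured on
    antibody suspension bead arrays in matched case-control cohorts:
    within-plate antibody-specific probabilistic quotient normalization and
    between-plate MA normalization of median fluorescence intensities,
    antibody quality control (replicate reproducibility, IgG correlation,
    background), covariate adjustment, archetypal-analysis clustering with
    knee-based model selection and bootstrap mean-Jaccard-index stability,
    cluster characterization (clinical tests, differential abundance with
    Benjamini-Hochberg correction, shortlisting, trait association), and
    conditional logistic regression for 1:M matched case-control sets.
    Includes a synthetic cohort and intensity-matrix generator that emulates
    the study structure (matched trios, replicate and repeated-visit samples,
    plate effects, planted archetypes and defective antibodies) so every
    stage is testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    nnet
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
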