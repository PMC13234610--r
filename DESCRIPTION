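Package: sustainz
Title: Subtype and Stage Inference for Regional Biomarker Z-Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits linear z-score event-sequence models of disease
    progression (Subtype and Stage Inference, SuStaIn) to regional
    biomarker data such as tau-PET SUVR. Regional values are z-scored
    against a control reference, per-region severity thresholds are
    derived by two-component Gaussian mixture modelling, and disease
    subtypes with their within-subtype event orderings are inferred
    jointly by expectation-maximization with divisive hierarchical
    clustering. Includes MCMC estimation of event-ordering uncertainty,
    cross-validated model selection, per-scan subtype and stage
    assignment with poor-fit exclusion, frozen-model restaging of
    longitudinal follow-up scans with stability metrics (confusion
    matrix, Cohen's kappa, annual stage-change rates), and a synthetic
    cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
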