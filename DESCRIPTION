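Package: dsebm
Title: Event-Based Staging of Preclinical Alzheimer's Disease in Down Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven staging of preclinical Alzheimer's disease in adults
    with Down syndrome from cross-sectional plasma biomarker and cognitive
    data. Implements an event-based model (EBM): per-marker normal/abnormal
    Gaussian mixture densities, a stage-marginalized sequence likelihood,
    greedy ascent plus Metropolis-Hastings sampling over event permutations,
    positional-variance summaries and individual disease staging. A companion
    age-trajectory arm provides predictive-mean-matching multiple imputation,
    Rubin-pooled principal component analysis, GAM and LOESS smooths with
    confidence bands, a pathology-aligned composite z-score and detection of
    the age window of maximal biomarker change. A synthetic cohort generator
    with a planted event ordering makes every stage of the pipeline testable
    without participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
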