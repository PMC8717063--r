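Package: dyadsync
Title: Inter-Brain Synchronization Analysis for Hyperscanning fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of dyadic (hyperscanning) fMRI
    experiments built around verbally cued joint-attention tasks. Provides a
    synthetic cohort generator with known inter-brain coupling ground truth,
    first-level general linear models (canonical double-gamma HRF, discrete
    cosine high-pass filtering, AR(1) restricted-maximum-likelihood
    prewhitening, condition-wise and trial-wise designs), beta-series and
    residual time-series inter-brain correlation with an exhaustive
    pseudo-pair null, and second-level inference (one-sample and Welch
    two-sample t maps, minimum-statistic conjunctions, and cluster-level
    family-wise error control by permutation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
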