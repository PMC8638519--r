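Package: imfp
Title: Infrared Molecular Fingerprinting of Blood Plasma for Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Case-control analysis of Fourier-transform infrared (FTIR) absorbance
    spectra of liquid blood plasma. Implements water-compensation baseline
    correction against a measured water reference, silent-region excision and
    Euclidean vector normalization, pooled-plasma quality-control drift
    monitoring, pairwise case-control covariate matching with standardized
    mean-difference balance diagnostics, per-wavenumber differential
    fingerprint statistics (mean difference, Glass-delta effect size, t-test
    p-values, Mann-Whitney U and per-wavenumber AUC), tumor-stage-stratified
    fingerprint comparison with enclosed-area ratios, and linear support-vector
    machine classification evaluated by repeated stratified k-fold
    cross-validation with vertically averaged ROC curves. A seeded generator of
    synthetic FTIR plasma cohorts with known ground truth supports end-to-end
    testing and power exploration without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    clue,
    pROC,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
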