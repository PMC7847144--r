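Package: msidiff
Title: Differential Metabolomics for MALDI Mass Spectrometry Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for tissue-type differential analysis of
    MALDI-TOF mass spectrometry imaging (MSI) data: imzML input/output with
    per-pixel histology annotations, spectral preprocessing (recalibration,
    TIC normalization, baseline correction, matrix-spectrum subtraction, peak
    selection with deisotoping, ppm-window peak-height extraction), orthogonal
    partial least squares discriminant analysis (OPLS-DA) with
    leave-one-patient-out cross-validation, permutation testing and variable
    importance on the projection (VIP) scores, and fraction-based iterative
    linear mixed models that defuse spatial autocorrelation by repeated
    subsampling, with Benjamini-Hochberg adjusted p values averaged across
    iterations and log2 fold changes. Includes a synthetic MSI generator with
    known ground truth for validation.
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
    rlang,
    readr,
    ggplot2,
    generics,
    xml2,
    jsonlite,
    Matrix,
    png,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
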