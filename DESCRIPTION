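Package: fractalstage
Title: Multifractal Spectrum Features and Nearest-Neighbour Staging of
    Brain Section Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Box-counting estimation of generalized dimensions and the
    Legendre singularity spectrum of two-dimensional measures derived
    from binarized brain-section images; extraction of a ten-feature
    multifractal signature (information and correlation dimensions,
    singularity-spectrum endpoints, spectrum width, symmetry shift and
    apparent section area); a from-scratch k-nearest-neighbour stage
    classifier with seeded split-and-average evaluation, confusion
    matrices, sensitivity/specificity/precision reports and one-vs-rest
    ROC/AUC; plus synthetic generators (multiplicative cascades with
    closed-form spectra, stage-parameterized brain phantoms, per-stage
    Gaussian feature tables) used to validate every step of the
    pipeline.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
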