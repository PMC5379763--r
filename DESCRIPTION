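Package: bactrace
Title: Segmentation, Tracking and Single-Cell Analytics for Bacterial
    Colony Time-Lapse Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fully automated analysis of time-lapse phase-contrast or
    bright-field "cell movies" of growing bacterial micro-colonies.
    Provides frame preprocessing (wavelet denoising, CLAHE), colony mask
    construction and colony tracking with merge detection, single-cell
    segmentation of dense touching-cell objects (skeleton-based shape
    classification, deep-valley splitting of collinear cell chains,
    watershed plus solidity-guided puzzle solving and Gaussian-mixture
    refinement with minimum-message-length model selection), a
    frame-to-frame cell tracker building lineage and divisions trees,
    single-cell growth analytics (exponential elongation fits,
    Baranyi-Roberts population kinetics, gamma life-attribute
    distributions), detection-quality evaluation against ground truth,
    a relational results store, and a seeded synthetic cell-movie
    generator with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    igraph,
    minpack.lm,
    fitdistrplus,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
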