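Package: CombiSurf
Title: Model-Based Synergy Analysis of Drug Combination Checkerboard Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis engine for drug-combination checkerboard assays read as
    matrices of percent-of-control response. Fits three-parameter Hill curves
    to the single-agent axes, derives non-synergistic reference surfaces under
    the Loewe additivity, Bliss independence and Highest Single Agent models,
    computes the synergy/antagonism distribution over concentration space,
    summarizes it with scalar metrics (maximum, integrated, effect-weighted
    integrated synergy and the concentration of peak synergy density), and
    batch-processes whole screens into a ranked metrics table. Includes a
    synthetic-data generator with known ground truth, publication plots, and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    ggplot2,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
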