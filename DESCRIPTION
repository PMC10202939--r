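Package: mechphen
Title: Mechano-Metabolic Phenotyping of 3D Cell Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for linking cytoskeletal mechanics,
    mitochondrial dynamics and metabolism in 3D cell migration studies.
    Implements direct 3D traction force microscopy on collagen reflectance
    stacks (block-matching particle image velocimetry, displacement-gradient
    strain, linear-elastic Cauchy stress, principal-stress traction maps),
    mitochondrial morphometrics (difference-of-Gaussian frequency
    decomposition with top-hat enhancement and per-object circularity;
    adaptive-threshold skeleton branch counting per cell), scalar cell and
    tissue scores (roundness, stain area fraction, adhesion percentage, 3D
    invasion index, ratiometric biosensor maps, histologic score, amoeboid
    score), and 1D NMR spectral preprocessing (segment-wise FFT peak
    alignment, probabilistic quotient normalization, pareto scaling, peak
    integration). Ships synthetic-data generators with stored ground truth
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    graphics,
    grDevices,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
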