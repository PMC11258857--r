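Package: redoxscreen
Title: Label-Free Metabolic Imaging Analysis for Cardiomyocyte Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for label-free optical metabolic imaging of
    iPSC-derived cardiomyocytes cultured on hydrogel substrates. Implements
    a background-normalized widefield optical redox ratio (ORR) workflow
    (rolling-ball illumination correction, cell masking, per-channel
    background normalization), a pixelwise biexponential TCSPC fluorescence
    lifetime (FLIM) fitting engine with instrument-response-function
    convolution and Poisson-weighted least squares, screen-level
    longitudinal statistics (trajectories, percent change, Welch's t-test),
    and a synthetic-data generator that produces widefield image pairs,
    photon-count decay cubes and whole longitudinal plates with known
    ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    jsonlite,
    minpack.lm,
    withr,
    Rcpp,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
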