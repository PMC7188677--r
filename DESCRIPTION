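Package: speckleflow
Title: Laser Speckle Contrast Imaging Analysis and Dynamic-Speckle Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for laser speckle contrast imaging (LSCI) of blood flow:
    spatial, temporal, and noise-reduced speckle contrast maps; motion-artifact
    frame rejection and exposure-validity masking; multi-exposure speckle
    imaging (MESI) fitting of the speckle correlation model to recover
    decorrelation times; relative flow quantification and vessel cross-section
    profiling; and a physics-grounded dynamic-speckle simulator with capillary
    and vessel phantoms so every stage can be validated against closed-form
    speckle statistics without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    minpack.lm,
    tiff,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
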