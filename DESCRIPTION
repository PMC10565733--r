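Package: isoclust
Title: Intensity-Based Hierarchical Clustering and Polymorph Detection for
    Multi-Crystal Diffraction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting structural polymorphs in multi-crystal
    macromolecular X-ray diffraction experiments. Continuous-rotation
    (helical) data sets are split into angular chunks, pairwise Pearson
    correlation coefficients of common reflection intensities are turned
    into distances, and Ward hierarchical clustering with a
    simulation-calibrated "isomorphic threshold" nominates candidate
    polymorph clusters. Includes the Monte-Carlo correlation-matrix
    simulation used to calibrate the threshold ratio, a unit-cell-based
    clustering companion with Tukey outlier filtering and linear cell
    variation reporting, and a synthetic-data generator with controlled
    within- and between-structure intensity correlation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
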