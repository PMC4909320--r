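Package: rootchamber
Title: Mass-Balance Modelling and 2D Root-System Phenotyping for
    Paper-Based Plant Growth Chambers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis toolkit for programmable, paper-based
    plant growth environments. Implements a steady-state mass-balance model
    of nutrient transport between a nutrient reservoir and the growth sheet
    (advective delivery, diffusive return, relative enrichment), a kinetic
    model of relative-humidity homeostasis by supersaturated salt solutions
    (including kinetic limitation and salt depletion), and a 2D root-system
    phenotyping pipeline on thresholded root images: projected area, root
    span (half the maximum Feret diameter), root symmetry (ratio of maximum
    perpendicular extents), and the size distribution of background areas
    fully enclosed by roots, with log-binned histograms, power-law tail
    fitting (Hill estimator), and permutation-based distribution
    comparisons. A seeded synthetic-data module generates root masks with
    known ground truth, spatial nutrient spot tables, and humidity time
    series so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    graphics,
    grDevices,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
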