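Package: zygopolar
Title: Quantitative Analysis of Intracellular Structure Polarity Along
    the Apical-Basal Axis of Plant Zygotes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An image-analysis pipeline for quantifying how intracellular
    structures (actin filaments, mitochondria, microtubules, vacuolar
    membranes) are distributed along the apical-basal axis of elongating
    Arabidopsis thaliana zygotes observed by time-lapse 3D fluorescence
    microscopy.  Time-lapse stacks are reduced to normalized axial
    intensity profiles via maximum-intensity projection, moment-based
    ellipse fitting and rotation, axial averaging, length standardization
    and z-scoring.  Profiles are assembled into a position-by-feature
    matrix, positions are compartmentalized into apical and basal domains
    by Ward (ward.D2) hierarchical clustering, domains are classified with
    a random forest (out-of-bag error, mean-decrease-Gini importance with
    Tukey-Kramer comparison across structures), and the position of the
    asymmetric cell division plane is quantified relative to the
    compartment boundary.  A synthetic-data generator produces elongating,
    rotated, noisy zygote movies with planted axial distributions and a
    known compartment boundary so that every stage is testable without
    real imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
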