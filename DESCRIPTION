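Package: nichekit
Title: Climatic Niche Comparison and Distribution Modelling on Gridded
    Environmental Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing climatic niches between two ranges of a
    species and for modelling its potential distribution. Implements
    environmental-space principal component analysis with kernel-smoothed
    occupancy grids, Schoener's D with equivalency and similarity
    permutation tests, expansion/stability/unfilling niche dynamics,
    three-dimensional convex-polyhedron and Bayesian ellipsoidal
    niche-region overlap with Monte-Carlo credible intervals, a
    maximum-entropy presence-background suitability model with L1
    regularization, candidate-model selection by partial ROC, omission
    rate and AICc, cross-scenario projection with bootstrap replicates,
    and four-way spread-stage classification. Includes a virtual-species
    generator producing landscapes and occurrence samples with known
    Gaussian niches so every stage can be validated against analytic
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    MASS,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
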