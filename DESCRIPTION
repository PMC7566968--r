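Package: ecophylo
Title: Phylogenetic Comparative Analysis of Hydraulic Safety and
    Photosynthetic Capacity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative eco-physiology of woody plants on a phylogeny:
    phylogenetic-signal estimation (Pagel's lambda with likelihood-ratio
    tests, phylogenetic signal representation (PSR) curves and areas, and
    white-noise/Brownian-motion/Ornstein-Uhlenbeck model selection by AIC),
    phylogenetic generalized least squares (PGLS) regression of traits on
    environmental gradients with maximum-likelihood branch-length
    transformation, principal component analysis of standardized climate
    variables, and phylogenetic quantile regression (PQR) with an
    inverse-distance-squared autocovariate for 10%/90% trait boundaries and
    outlier classification of threatened species.  Also fits non-rectangular
    hyperbola light-response curves and sigmoidal xylem vulnerability curves
    (P50), and computes branchlet hydraulic metrics.  Includes a synthetic
    data generator (trees, traits, environments, planted outliers, noisy
    curves) with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    igraph,
    withr
Config/testthat/edition: 3
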