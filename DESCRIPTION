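Package: rangecast
Title: Ensemble Species Distribution Modelling with Bias-Aware
    Pseudo-Absences and Dispersal-Bounded Range Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for ensemble species
    distribution modelling from presence-only records: occurrence cleaning
    and spatial thinning, observer-bias-aware pseudo-absence generation
    (environmental-kernel complement weighted by a sampling-effort layer),
    stepwise variance-inflation-factor predictor selection, a multi-algorithm
    suitability roster (climate envelope, regression, tree, ensemble-tree,
    neural-network and discriminant learners) evaluated by AUC, TSS, Kappa
    and the continuous Boyce index, threshold-gated TSS-weighted ensembling,
    projection onto climate scenarios with dispersal-bounded range-change
    estimates, and MESS extrapolation diagnostics.  Ships a synthetic
    landscape generator with a known true niche so that every stage is
    testable against ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    rpart,
    randomForest,
    nnet,
    xgboost,
    MASS,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
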