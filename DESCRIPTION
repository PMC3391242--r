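Package: gridsdm
Title: Ensemble Species Distribution Modelling on Atlas Grid Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An ensemble framework for modelling species distributions from
    grid-cell (atlas) presence/absence data. Provides explicit predictor
    selection (PCA representatives, pairwise-correlation capping, univariate
    discrimination screening and a three-criteria relevance rule), four niche
    model engines (stepwise logistic regression, fixed-df spline additive
    models, bagged classification trees, and a presence-only maximum-entropy
    model), repetition-based split validation with sensitivity/specificity
    equalising thresholds, majority-vote consensus mapping, fuzzy c-means
    grouping of species' environmental responses, and climate-scenario
    projection with range loss/gain and novel-climate (extrapolation)
    accounting. A synthetic-grid module generates spatially smooth predictor
    fields and virtual species with known occupancy probabilities so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    splines,
    ranger,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
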