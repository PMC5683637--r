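Package: virtualSDM
Title: Virtual Species Simulation for Benchmarking Species Distribution
    Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A virtual-ecologist workbench for presence-background species
    distribution modelling (SDM). Generates seeded, spatially autocorrelated
    and collinear synthetic environmental raster stacks at two grid
    resolutions, builds virtual species with controlled ecological
    specialisation as Gaussian niches on the first two principal-component
    axes, samples occurrences with a binomial acceptance rule and injects
    controlled positional error, fits five SDM algorithm families (GLM, GAM,
    boosted trees, random forest, Maxent-style penalised logistic) under
    five-fold cross-validation with replicated background sets, and
    quantifies both performance (AUC, True Skill Statistic) and reliability
    (Schoener's D niche overlap, overall concordance correlation
    coefficient) against the known true ranges, including the downstream
    Wilcoxon comparisons and the exp(AUC) linear factor analysis with AIC
    model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    mgcv,
    randomForest,
    xgboost,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'grid-io.R'
    'synthetic-env.R'
    'virtual-species.R'
    'occurrence-sampler.R'
    'predictor-prep.R'
    'sdm-engine.R'
    'metrics.R'
    'experiment.R'
    'stats-report.R'
    'utils.R'
    'virtualSDM-package.R'
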