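Package: qsrrkit
Title: Retention-Time QSRR Modeling with Stacked Ensembles and a kNN
    Applicability Domain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative structure-retention relationship (QSRR)
    modeling of small-molecule retention times in reversed-phase liquid
    chromatography across multiple mobile-phase pH conditions. Provides
    pH-dependent descriptor construction by microspecies-fraction weighting,
    data cleaning and leak-free standardization, correlation-based and
    recursive-feature-elimination selectors with a cross-method consensus,
    five tunable base learners benchmarked under cross-validated grid
    search, a two-level stacked ensemble with a linear meta-learner, and a
    k-nearest-neighbour applicability-domain filter with percentile
    thresholds. A seeded synthetic-data generator emulating the statistical
    structure of small chromatographic datasets makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
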