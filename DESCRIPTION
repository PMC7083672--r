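Package: chsdm
Title: Comprehensive Habitat Suitability Modelling with TSS-Weighted Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Species distribution modelling pipeline for comprehensive
    habitat suitability (CHS) analysis. Fits an ensemble of ten
    presence/pseudo-absence algorithms weighted by the true skill
    statistic, gates the continuous ensemble suitability surface by a
    categorical maximum-entropy soil suitability model and a binary
    vegetation mask, projects the fitted ensemble onto future climate
    scenarios (GCM by RCP), and reports zonal habitat areas and
    class-transition summaries. Ships a synthetic-world generator (random
    climate fields, derived terrain, categorical soil/vegetation mosaics,
    and a virtual species with a known niche) so the whole pipeline is
    testable end to end without external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    mgcv,
    nnet,
    rpart,
    ranger,
    xgboost,
    glmnet,
    geosphere,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
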