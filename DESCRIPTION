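Package: esdm
Title: Ensemble Species Distribution Modelling for Coastal Line-Transect Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the spatial distribution of coastal marine
    megafauna from systematic line-transect surveys. Converts survey tracklines
    and sightings into a gridded presence/absence response with effort-ranked
    true-absence selection, derives ecogeographic predictor layers (Euclidean
    and land-aware cost distances, terrain derivatives, ordinary kriging,
    categorical benthic habitat), screens predictors for collinearity (vifcor
    and vifstep), fits an AUC-weighted ensemble of six presence/absence
    classifiers with permutation variable importance, and assesses overlap of
    high-occurrence areas with marine-park sanctuary (no-take) zones by
    randomization test. Includes a synthetic-data generator emulating a shallow
    coastal study area surveyed with zig-zag transects, so the whole pipeline
    is testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    splines,
    jsonlite,
    mgcv,
    rpart,
    randomForest,
    xgboost,
    glmnet,
    MASS
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
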