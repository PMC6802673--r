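Package: fetalbone
Title: Classification of Fetal Bone Development from Serum Bone-Turnover Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for predicting fetal and maternal bone phenotype
    classes (femur and humerus weight, length, diameter) from six serum
    bone-turnover biomarkers measured under a 2x2x2 factorial design (animal
    type, maternal nutrition treatment, gestation period). Implements
    experiment-centered feature engineering (group-mean-centered biomarkers),
    one-hot and probability encodings of the experimental conditions, a
    factory for feature-block combination datasets, a leave-one-out
    cross-validation harness over seven classifier families, removal-based
    feature importance, single-feature models, and a synthetic-data generator
    with planted effects for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    glmnet,
    rpart,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
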