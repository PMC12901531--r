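Package: segrecov
Title: Clustered Cross-Validation Evaluation of Segmental Myocardial
    Recovery Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluation workflow for predicting segmental myocardial
    wall-motion recovery after revascularization from ordinal PET/MRI
    viability scores (FDG uptake, LGE scar transmurality, wall-motion
    abnormality), with the inference machinery required by segments
    nested in subjects: a clustered ROC AUC with a components-based
    variance estimator, a combined 5x2 cross-validation F-test for
    clustered matched-pair marginal success probabilities, exact
    model-agnostic Shapley attributions aggregated to a Global Absolute
    Shapley summary, grouped-stratified repeated cross-validation with
    minority oversampling, and a synthetic clustered cohort generator
    calibrated to the association structure of the motivating study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    lme4,
    randomForest,
    rpart,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
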