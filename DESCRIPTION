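Package: otobias
Title: Bias Audits for Binary Medical-Image Classification Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Audit toolkit for detecting shortcut-learning hazards in binary
    medical-image classification datasets, with otoscopy as the motivating
    application. Implements counterfactual occlusion masking with a parametric
    elliptical "eclipse" mask, an HSV color-statistic confound audit based on
    logistic regression with Wald odds-ratio inference, DeLong AUC variance,
    confidence intervals and paired/unpaired AUC comparison tests, and an
    embedding-based near-duplicate and stylistic-bias analysis using
    cosine-distance threshold grouping. Ships a synthetic otoscope-like image
    generator with planted, ground-truthed biases (class-correlated saturation
    variability, framing styles, near-duplicate sets with optional cross-split
    leakage) so every audit component can be validated at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    png,
    jsonlite,
    igraph,
    glmnet,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
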