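Package: themelasso
Title: Iterative Thematic Analysis for High-Dimensional Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Survey-weighted penalized logistic regression with iterative
    theme-based feature exclusion for rare binary outcomes in complex
    survey data. Implements lasso pre-filtering, ridge ranking,
    curvature-based knee-point selection on the ranked coefficient
    curve, human-in-the-loop theme coding with qualification and
    exclusion rules, explicit stopping criteria, and a feed-forward
    neural-network variant that ranks inputs by first-hidden-layer
    weight importance. Includes a synthetic survey-data generator with
    planted latent themes, redundant variable representations,
    heterogeneous sampling weights and a calibrated rare outcome, so the
    full pipeline can be exercised and validated by parameter-recovery
    experiments without access-restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
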