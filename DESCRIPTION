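Package: mivarsel
Title: Variable Selection for Prediction Models with Multiply Imputed Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating logistic prediction models when
    covariates are incomplete and handled by multiple imputation. Provides
    multiple imputation by chained equations (predictive mean matching for
    continuous variables, logistic draws for binary variables), L1-penalized
    logistic regression with cross-validated penalty selection (optimal and
    one-standard-error rules) on separate or stacked imputed data with
    observation weights and subject-grouped folds, bootstrap variable
    inclusion-frequency selection with lasso or AIC backward elimination,
    recalibration of over-shrunk models by score or by refitting selected
    variables, external predictive evaluation (AUC, Brier score, selection
    counts), enhanced-bootstrap optimism correction that repeats imputation
    and selection inside each resample, and a simulation engine with two
    covariate-generating mechanisms and a missing-at-random missingness model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
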