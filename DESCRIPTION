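Package: craniospring
Title: Finite-Element Simulation and Surrogate Modelling for Spring-Assisted Cranioplasty Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning spring-assisted correction of sagittal
    craniosynostosis. Builds a parametric hexahedral finite-element model of
    an infant calvarium with compliant suture and fontanelle regions, applies
    a parasagittal osteotomy and compressed expansion springs, and solves the
    linear-elastic equilibrium to predict the immediate post-operative
    cephalic index. A simulation campaign sampled over surgical and material
    parameters trains six regression surrogates (linear regression, support
    vector regression, decision tree, random forest, gradient boosting,
    XGBoost) whose hyperparameters are tuned by a tree-of-Parzen-estimators
    optimiser, so that post-operative outcomes can be predicted without
    re-running the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
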