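Package: serojm
Title: Joint Models of Longitudinal Serological Markers for Dynamic
    Survival Prognostication in Metastatic Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dynamic prognostication in metastatic
    hormone-sensitive prostate cancer from longitudinal serological
    markers (hemoglobin, neutrophil-to-lymphocyte ratio,
    platelet-to-lymphocyte ratio, lymphocyte-to-monocyte ratio, and
    prostate-specific antigen). Provides a synthetic trial-cohort
    generator with a monthly-then-bimonthly visit schedule, linear
    mixed-effects sub-models per marker, Cox proportional-hazards
    sub-models, univariate and multivariate joint longitudinal-survival
    models with a current-value association (full-likelihood estimation
    via adaptive Gauss-Hermite quadrature, a fast two-stage
    approximation, and a Bayesian backend with horseshoe shrinkage on
    the association coefficients), landmark dynamic predictions of
    conditional survival, five-fold cross-validated evaluation with
    inverse-probability-of-censoring-weighted Brier scores and
    calibration indices (ICI, E50, E90), and decision-curve analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    survival,
    statmod,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    numDeriv,
    withr
Config/testthat/edition: 3
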