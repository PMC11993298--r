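Package: cocktailpk
Title: Microdose Cocktail Population Pharmacokinetics and Transporter
    Activity in End-Stage Renal Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for microdose probe-drug
    cocktail studies of drug-metabolizing enzyme and transporter (DMET)
    activity in end-stage renal disease. Provides a closed-form
    two-compartment oral pharmacokinetic model, a seeded synthetic-cohort
    generator (demographics, labs, gut-microbiome genus abundances,
    transporter genotypes), non-compartmental exposure analysis with
    linear-up/log-down AUC, nonlinear mixed-effects population models with
    covariate effects, MAP Bayes individual estimation, Laplace-type
    population refitting, bootstrap and visual predictive checks, and
    closed-form translation of model estimates into OATP1B, intestinal
    P-gp, BCRP and CYP3A activity changes, plus a correlation/LASSO
    covariate-selection stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
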