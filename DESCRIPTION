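Package: prismsurv
Title: Tree-Structured Moderation Models for Right-Censored Survival Disparities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits tree-structured varying-coefficient regression models for
    right-censored log survival times (PRISM), in which individual-level
    covariates recursively partition the cohort and a focus-variable
    regression (e.g. a race contrast) is estimated within each partition cell
    by Kaplan-Meier (Stute) weighted least squares. A hierarchical extension
    (HPRISM) adds a focus-by-contextual interaction with an area-level social
    determinant, capturing multilevel moderation. Includes censored-residual
    split search and a log-rank alternative, Harrell's C evaluation over
    repeated censoring-stratified holdouts, permutation-based local variable
    importance with Andrews-curve visualization, specific area-level disparity
    estimates (SPADE) with composite and robust-z summaries, a multilevel
    synthetic-data generator, and descriptive cohort comparison fits
    (chi-squared, Fisher, binary/multinomial logit, proportional odds).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    MASS,
    nnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
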