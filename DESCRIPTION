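Package: medroute
Title: Causal Mediation of the Comorbidity Gap in Lymphoma Survival by
    Diagnostic Route
Version: 0.1.0
Authors@R:
    person("Registry", "Methods", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for decomposing the total effect of comorbidity on
    mortality in population-based cancer registry cohorts into natural
    direct and indirect effects acting through the diagnostic route
    (emergency versus elective presentation). Provides a synthetic
    registry cohort generator with an exact enumeration oracle for the
    true natural effects, Table-1 style descriptive statistics with Wald
    odds ratios, Pohar Perme net survival estimation against a life
    table, Monte Carlo g-computation of marginal natural effect odds
    ratios with single stochastic imputation of the missing mediator,
    the proportion mediated on the odds-ratio scale, percentile
    bootstrap intervals, and a config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    optparse
Suggests:
    survival,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
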