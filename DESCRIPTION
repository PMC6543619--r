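Package: trajectsim
Title: Discrete-Time Multistate Microsimulation of Chronic Disease
    Trajectories from Registry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building, estimating and validating discrete-time
    state-transition microsimulation models of chronic disease trajectories
    from registry-style follow-up data, with prostate cancer as the worked
    disease model. Provides an irreversible treatment-state graph with
    ordinal risk categories, expansion of dated patient records into
    four-week person-period format with time-updated age and comorbidity,
    logistic, multinomial, ordinal and zero-truncated Poisson
    transition-probability estimation with multiple imputation by chained
    equations and Rubin pooling, a fast individual-level simulation engine
    with reproducible counter-based random-number substreams, a
    synthetic-registry generator with known ground truth, and
    competing-risks cumulative-incidence machinery for
    observed-versus-simulated internal validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cmprsk,
    survival,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
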