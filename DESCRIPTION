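Package: adaptod
Title: Model-Based Adaptive Optimal Design Simulation for Dose-Finding
    PKPD Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates model-based adaptive optimal design (MBAOD) of
    dose-finding trials driven by a nonlinear mixed-effects PKPD model.
    Provides first-order (FO) Fisher information matrices for population
    models, local (lnD) and robust (ELD/API) design criteria with Latin
    hypercube integration over a parameter prior, exhaustive discrete
    dose optimization, in-package FO and FOCEI maximum-likelihood
    estimation, a multivariate-t stopping rule on the precision of the
    typical effect prediction, and design-efficiency evaluation against
    the true-parameter optimal design trajectory.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    generics,
    lhs,
    mvtnorm,
    numDeriv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
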