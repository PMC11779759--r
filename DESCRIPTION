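Package: gridmcct
Title: Termination Criteria for Between-Item Grid Multidimensional
    Computerized Classification Tests
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation toolkit for between-item grid multidimensional
    computerized classification tests (MCCT) under the three-parameter
    logistic (3PL) item response model.  Implements sequential probability
    ratio test (SPRT) termination criteria: the per-dimension SPRT (SPRT-SF),
    the SPRT with conditional latent-trait imputation of non-target
    dimensions (SPRT-C), and a pre-rule (P-SPRT) that switches between them
    based on the sign of the correlation-weighted product of provisional
    trait deviations from the cutoffs.  Includes Segall-style Bayesian item
    selection by the determinant of the posterior information matrix at the
    cutoff vector, maximum-likelihood trait estimation, item-bank and
    examinee generators, full simulation-condition runners with
    classification-accuracy and test-length metrics, operating-characteristic
    curves, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
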