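Package: dtpln
Title: Inference for the Mean of the Delta-Three-Parameter Lognormal Distribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Point and interval estimation for the mean of a delta-three-parameter
    lognormal (DTPLN) model for nonnegative data with exact zeros, such as weekly
    rainfall totals: an observation is zero with probability delta, otherwise it is
    a threshold a plus a lognormal amount. Provides the modified-moment threshold
    estimator of Cohen and Whitten, maximum likelihood estimates of the remaining
    parameters, and six confidence intervals for the log-transformed mean:
    equal-tailed and highest-posterior-density intervals under two noninformative
    priors, a generalized (fiducial) confidence interval built from generalized
    pivotal quantities, and a closed-form MOVER interval combining a Wilson score
    interval for the zero proportion with component intervals for the positive part.
    Includes a Monte Carlo engine that measures coverage probability and expected
    length over parameter grids, AIC/BIC screening of candidate distributions for
    the positive part, and a packaged rainfall data set from northern Thailand.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
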