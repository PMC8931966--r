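Package: rmstpv
Title: Restricted Mean Survival Time Difference Curves via Pseudo-Values
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Model-based estimation of the difference between restricted
    mean survival time (RMST) curves over follow-up time. Jackknife
    pseudo-values of the Kaplan-Meier RMST are computed at a grid of
    restriction times and regressed with identity-link generalized
    estimating equations under an independence working correlation, with
    cluster-robust (sandwich) variance. Baseline RMST and time-varying
    covariate effects are modelled with restriction-time indicators or
    natural cubic splines; quasi-information-criterion (QIC) selection of
    the spline dimension, pointwise confidence intervals, and max-t
    simultaneous confidence bands for the difference curve are provided,
    together with simulation tools for right-censored Weibull and
    piecewise-exponential survival data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    splines,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
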