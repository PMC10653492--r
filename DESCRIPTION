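Package: ggfrailty
Title: Penalized Estimation of the Gamma-Gompertz Frailty Model for
    Detecting Mortality Deceleration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the gamma-Gompertz frailty model to life-table data
    (death counts and person-years exposures) by maximum likelihood and by
    a penalized likelihood (maximum a posteriori) estimator whose penalty
    on the frailty variance shrinks it exactly to zero when death rates
    show no old-age deceleration.  Includes closed-form Gompertz and
    gamma-Gompertz hazard, survival and quantile functions, a cohort
    lifespan simulator, a Monte Carlo study engine for estimator bias,
    standard deviation and detection-error rates, Wald standard errors and
    confidence intervals from the observed information, goodness-of-fit by
    mean squared error on the log death-rate scale, readers for CSV and
    Human Mortality Database style life tables, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    flexsurv
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
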