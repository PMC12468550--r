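Package: tvarnet
Title: Time-Varying Autoregression by Neural-Network, Basis-Expansion and
    Kernel Estimators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation, simulation and forecast benchmarking of time-varying
    autoregressive (TV-AR) and time-varying vector autoregressive (TV-VAR)
    models, in which the intercept and lag coefficients are smooth functions
    of time rather than constants.  Four estimators share one interface: a
    feed-forward neural network that maps normalized time to the coefficient
    vector and is trained by minimizing the autoregressive residual loss with
    L-BFGS-B; a basis-expansion (varying-coefficient) estimator fitted by
    constrained least squares; one-sided Gaussian-kernel smoothing at the
    series endpoint with cross-validated bandwidth; and a stationary
    ordinary-least-squares baseline.  Includes synthetic data generators with
    sigmoid-like and quadratic coefficient drift, recursive multi-step
    forecasting and full-trajectory reconstruction, and a Monte-Carlo
    benchmark harness reporting mean absolute error and the root sample
    variance of absolute errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
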