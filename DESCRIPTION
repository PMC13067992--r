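Package: ildsmooth
Title: Non-Parametric Trend Estimation for Intensive Longitudinal Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating non-linear trends in intensive longitudinal
    data (e.g. ecological momentary assessment series) with local polynomial
    regression, Gaussian-process regression, penalized-spline generalized
    additive models, and a global polynomial baseline, each returning pointwise
    estimates, standard errors, 95% intervals and the smoother's hat matrix.
    Includes a stochastic differential equation simulator (Euler-Maruyama) for
    four exemplar latent processes (exponential growth, logistic growth, cusp
    catastrophe, damped oscillator) with Wiener-process dynamic errors and
    Gaussian measurement error, evaluation machinery (MSE, hat-matrix GCV,
    interval coverage, Monte-Carlo standard errors, partial eta-squared ANOVA
    summaries), a factorial simulation-study runner, and an idiographic
    screening stage that classifies per-person trends by the effective degrees
    of freedom of a GAM smooth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
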