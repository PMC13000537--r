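Package: cortcurve
Title: Model-Based Indicators of the Salivary Cortisol Stress Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits gamma-kernel models of the salivary cortisol response to
    acute laboratory stressors and derives model-based summary indicators
    (area under the curve with respect to ground and increase, reactivity,
    maximum increase) that are robust to heterogeneous saliva sampling
    schedules. Provides an amplitude scaling model that rescales a
    population-average response curve per individual, a nonlinear
    multilevel model with empirical-Bayes shrinkage and covariate effects,
    observation-based indicator calculators, a stochastic cohort simulator
    with red (synthesis) and white (measurement) noise integrated by the
    Euler-Maruyama method, and evaluation tools for rank-order accuracy,
    cross-schedule stability, combined-data bias and sampling-duration
    bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
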