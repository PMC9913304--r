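Package: survtrend
Title: Long-Term Registry Survival Trend Analysis
Version: 0.1.0
Authors@R:
    person("Registry", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for long-term cancer-survival trend analysis from
    registry-style data: simulation of individual-level cohorts with
    configurable excess-hazard trends, age-standardized net (relative)
    survival via the Pohar Perme estimator with cohort and hybrid period
    designs, world-standardized incidence rates and cumulative risks,
    Bayesian measurement-error penalized-spline smoothing of period-wise
    survival estimates over calendar time, posterior conditional (5/1-year)
    survival, annual-change curves, plausible-trend intervals and
    breakpoint detection from derivative credible bands, plus readers and
    writers for registry-export style CSV files and a staged pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
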