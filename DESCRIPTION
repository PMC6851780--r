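Package: spirosim
Title: Monte Carlo Simulation of Measurement Error in Spirometric Testing
    Protocols
Version: 0.1.0
Authors@R:
    person("spirosim", "maintainers", email = "spirosim@example.org",
           role = c("aut", "cre"))
Description: Simulates forced expiratory volume (FEV1) testing under the
    ATS/ERS spirometry protocol to quantify the measurement error created by
    repeatability criteria and early test termination. Provides a two-level
    normal variability model (intertest and intratest coefficients of
    variation), the iterative repeatability-criterion selection algorithm
    with configurable stopping rules and missing-data policies, analytic
    repeatability-failure probabilities, exclusion-rate arithmetic for
    published maneuver-count tables with grid inference of the intratest
    coefficient of variation, and minimum-detectable-difference thresholds
    for before/after comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
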