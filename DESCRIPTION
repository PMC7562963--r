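Package: irrisim
Title: Greenhouse Irrigation Strategy Evaluation Under Soil and
    Evapotranspiration Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates vertical soil water dynamics in a greenhouse soil
    column with a mass-conservative implicit solver for the Richards
    equation, closed by Mualem-Van Genuchten hydraulic functions and driven
    by a radiation/heating-pipe (De Graaf) evapotranspiration model with a
    root water uptake sink.  A Monte Carlo engine propagates uncertainty in
    daily evapotranspiration (bootstrap resampling) and in soil identity
    (categorical draws from a soil-type catalogue) into per-strategy
    predictions of drainage, water use and a crop water-stress ratio, so
    that competing irrigation schedules can be ranked under uncertainty.
    Includes a synthetic fixture generator for forcing series and soil
    catalogues so the package is fully testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
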