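Package: neogrowth
Title: Agreement Between Exponential-Model and Z-Score Growth Velocity in
    Preterm Infants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the two metrics commonly used to quantify
    weight-gain velocity of preterm infants during the neonatal hospital stay:
    the exponential-model rate in g/kg/d (1000 * ln(Wn/W1) / days) and the
    change in weight z-score against a sex-specific LMS growth reference.
    Provides LMS chart handling with day-level age interpolation, per-infant
    velocity computation, an ordinary-least-squares calibration that expresses
    the z-score metric in g/kg/d units, Bland-Altman limits of agreement with a
    tiered fair/poor/disagreement classification, multivariable regression of
    the per-infant method difference on clinical characteristics with
    variance-explained decomposition, and a seedable synthetic cohort and chart
    generator so the whole pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
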