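Package: beachrisk
Title: Multi-Route Cancer Risk Assessment for Children Playing on
    Oil-Contaminated Beaches
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic dose and lifetime excess cancer risk
    calculations for oral, dermal, and inhalation exposure of children to
    an oil-spill chemical in beach media (sediment, weathered oil, tar),
    following the standard environmental risk-assessment dose equations.
    Includes Monte Carlo uncertainty propagation over triangular
    (minimum, likeliest, maximum) parameter distributions, a synthetic
    child-cohort generator with min/median/max distillation back into
    triangular inputs, YAML scenario configuration with bundled
    scenarios, and report rendering plus a small command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
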