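Package: resusim
Title: Software Testbed for Closed-Loop Hemorrhage Resuscitation Controllers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pure-software benchtop simulator for developing and scoring
    closed-loop fluid-resuscitation controllers under hemorrhagic shock.
    Provides a hydrostatic pressure-volume plant whose vessel geometry is
    designed from a target mean-arterial-pressure versus infused-volume
    curve (linear for whole blood, parabolic for crystalloid), an automated
    outflow engine combining pressure-dependent hemorrhage, coagulation
    decay, over-pressure re-bleed penalties and basal urine output, a
    reference six-step decision-table infusion controller with configurable
    sampling period, four chained test scenarios (initial bleed, tourniquet
    failure, vasopressor bolus, non-clotting coagulopathy), and a
    twelve-metric controller performance report including the Varvel
    statistics (MDPE, MDAPE, wobble, divergence) and area-to-setpoint
    measures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
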