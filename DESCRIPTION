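Package: glucosim
Title: Virtual Clinical Trials for Closed-Loop Glucose Control Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A glucoregulatory simulator for developing and stress-testing
    single- and dual-hormone artificial-pancreas dosing algorithms in type 1
    diabetes. Implements a seven-subsystem, thirteen-state ordinary
    differential equation model of subcutaneous insulin and glucagon
    pharmacokinetics, insulin action, gut glucose absorption, plasma and
    interstitial glucose dynamics, with piecewise-linear diurnal flux
    functions for intra-day variability. Provides a synthetic virtual-patient
    cohort generator, a protocol-driven trial engine with a two-method
    controller contract, fault isolation and rescue-carbohydrate handling,
    reference open-loop and closed-loop controllers, and the standard battery
    of glycemic outcome metrics (time in range, hypo-/hyperglycemia exposure
    and incidence, glycemic variability, hormone delivery).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
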