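Package: dxa4c
Title: Four-Compartment Body Composition Reference Model and DXA Agreement
    Analysis
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the four-compartment (4C) molecular body-composition
    reference model (fat, water, mineral, protein) with its component-density
    decomposition, technical-error-of-measurement propagation, and the full
    method-comparison toolkit (Bland-Altman limits of agreement, regression
    against the line of identity, paired and one-sample tests, correlation
    power) used to validate dual-energy X-ray absorptiometry (DXA) against
    the 4C criterion, both cross-sectionally and for change tracking. A
    calibrated synthetic two-phase athlete-cohort generator makes every
    pipeline stage testable without access to raw measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
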