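Package: braggmap
Title: Spatial Mapping of Proton Beam Biologic Effectiveness with
    High-Throughput Clonogenic Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping the biologic effectiveness of scanned
    monoenergetic proton beams along the Bragg curve. Implements an
    analytic one-dimensional transport model (Bragg-Kleeman range-energy
    law with Gaussian range spread) for a 12-step Lucite range-shifter
    jig that exposes each column of a 96-well plate to a distinct dose
    and dose-averaged linear energy transfer (LET); event-level
    dose-averaged LET scoring from (energy deposition, step length)
    pairs; clonogenic survival analysis with weighted linear-quadratic
    fits, SF2, D10 and relative biological effectiveness (RBE) with
    propagated uncertainty; extra sum-of-squares F tests for curve
    comparison; a setup-uncertainty sensitivity analysis; and a
    synthetic 96-well colony-count generator so that the full pipeline
    is testable without beam time.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
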