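Package: scsolub
Title: Solubility Modeling of Drugs in Supercritical Carbon Dioxide
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Correlates solute solubility in supercritical carbon dioxide
    with six density-based semi-empirical models (Chrastil, Bartle,
    Kumar-Johnston, Mendez-Santiago-Teja, Sodeifian, Jouyban) and a
    modified Wilson expanded-liquid model.  Parameters are estimated by
    simulated annealing with a derivative-free simplex polish; fits are
    scored by the average absolute relative deviation (AARD%) and the
    adjusted correlation coefficient.  Includes mixing/vaporization/
    solvation enthalpy extraction from the fitted temperature
    coefficients, crossover-pressure and self-consistency diagnostics, a
    synthetic-data generator for parameter-recovery studies, and the
    aripiprazole solubility dataset (308-338 K, 12-30 MPa) as a bundled
    fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
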