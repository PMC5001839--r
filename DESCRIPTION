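Package: chromatophore
Title: Energy Conversion Modelling of Purple-Bacterial Chromatophore Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the complete light-to-ATP energy conversion chain of a
    low-light-adapted purple-bacterial chromatophore vesicle. Generates
    synthetic vesicle geometries (LH2, RC-LH1-PufX, cytochrome bc1 and ATP
    synthase complexes placed on a sphere, with bacteriochlorophyll ring
    coordinates and transition dipoles), builds per-complex exciton
    Hamiltonians and inter-complex generalized Foerster transfer rates,
    computes the light-harvesting quantum yield by a rate-matrix linear solve
    backed by an independent time-propagation oracle, evaluates a
    steady-state kinetic model of quinone cycling limited by cytochrome bc1
    turnover to obtain ATP synthesis rates and energy conversion efficiencies
    versus light intensity, and sweeps vesicle composition at fixed membrane
    area to map the optimality landscape of ATP production.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
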