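Package: dibkit
Title: Drug-Membrane Interaction Analysis from Droplet Interface Bilayer,
    Calorimetry, and Raman Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how small amphipathic drugs such as
    aspirin perturb lipid bilayers, built around three bench measurements:
    osmotic water permeability of droplet interface bilayers (forward
    simulation of osmotically unbalanced droplet pairs and inversion of
    observed shrinkage to a permeability coefficient), interfacial
    energetics from droplet contact geometry (bilayer tension, Young-Dupre
    free energy of bilayer formation, lateral pressure), differential
    scanning calorimetry thermogram analysis (baseline subtraction, main
    transition temperature and enthalpy), and Raman C-H stretching order
    ratios with scaled reference subtraction of drug bands.  Seeded
    synthetic-data generators emulate all three modalities so every stage
    of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
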