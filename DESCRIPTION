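Package: gemflux
Title: Constraint-Based Metabolic Modeling for Denitrifying Polymer Producers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building, quality-controlling and interrogating
    genome-scale metabolic models of denitrifying, polymer-producing bacteria.
    Includes homology-hit calibration and multi-template draft merging, model
    quality control (mass/charge balance, dead-end metabolites, energy-generating
    cycles), flux balance analysis with growth-condition constraints, phenotype
    panel prediction with growth-level classification, single gene and reaction
    deletion screens, artificial-centering hit-and-run flux sampling with
    subsystem regulation statistics, and polyhydroxybutyrate/exopolysaccharide
    yield analysis under carbon-to-nitrogen and oxygen constraints. Ships seeded
    generators for toy networks with denitrification, DNRA, aromatic degradation
    and polymer branches so every analysis is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
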