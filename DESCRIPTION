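Package: lkcbm
Title: Constraint-Based Analysis of Yeast Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, curating and interrogating constraint-based
    metabolic models of budding yeasts, with an emphasis on weak Crabtree
    positive physiology (respiration/fermentation trade-off, ethyl acetate
    overflow, uracil catabolism as a nitrogen source). Provides a metabolic
    model container with SBML and JSON readers and writers, curation operators
    (mass and charge balance checks, reversibility rules, blocked reaction
    detection, biomass precursor producibility, confidence scoring, pathway
    insertion), flux balance analysis with flux variability and loopless flux
    variability, minimization of metabolic adjustment, dynamic batch
    fermentation simulation, gene-essentiality screening with classification
    statistics, GIMME context-specific model extraction with Jaccard-interval
    differential flux analysis, growth-rate estimation from optical density
    time courses, and seeded synthetic-data generators so the whole pipeline
    is exercisable on toy networks with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    quadprog,
    stats,
    utils,
    xml2
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
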