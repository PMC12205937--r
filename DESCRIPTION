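Package: cofactory
Title: Multi-Constraint Metabolic Simulation and Production Forecasting
    for Two-Strain Microbial Consortia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based simulation of two-strain microbial cell
    factories. Combines flux balance analysis with an enzyme-pool kinetic
    constraint and a max-min driving force (MDF) thermodynamic program to
    simulate mono-culture fluxes, calibrates biosynthesis-pathway
    expression degrees (the fractional growth loss caused by forced
    pathway expression) against measured titers, maps mean mono-culture
    fluxes to instantaneous co-culture fluxes through a substrate-derived
    mapping constant, integrates product formation over the co-culture
    horizon with cross-feeding bookkeeping, and ranks metabolic
    engineering levers by finite-difference sensitivity analysis.
    Includes pathway-level thermodynamic reporting (MDF, bottleneck
    reactions, metabolite shadow prices) and fit metrics for comparing
    predictions with experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
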