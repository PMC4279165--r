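Package: foldtrap
Title: Kinetic Analysis for Chaperonin-Capture Protein Folding Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing solid-phase chaperonin (GroEL) kinetic-trap
    experiments on metastable proteins such as frataxin clinical variants.
    Provides a mass-action kinetic model of native/intermediate exchange with
    irreversible chaperonin capture and a competing aggregation channel,
    pseudo-first-order fits of soluble-fraction time courses, hyperbolic
    saturation analysis of apparent partitioning rates versus chaperonin
    concentration, two-state van 't Hoff fits of thermal-unfolding curves
    (equilibrium and differential scanning fluorimetry) with osmolyte
    melting-temperature-shift summaries, UV-visible light-scattering quality
    control, densitometry-based solubility arithmetic, and seeded synthetic
    data generators for every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
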