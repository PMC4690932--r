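Package: settleflux
Title: Activated-Sludge Thickening and Settling Models for Secondary Clarifiers
Version: 0.1.0
Authors@R:
    person("settleflux", "developers", email = "settleflux@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the thickening and settling of activated
    sludge in secondary clarifiers. Calibrates a power-law model of the
    bottom (thickened) sludge concentration from batch thickening tests,
    links its coefficient to the sludge volume index (SVI) across plants,
    derives compression settling velocities from the mass balance of the
    sludge blanket, combines them with a Vesilind hindered-settling law
    into an integrated piecewise velocity model with graphical
    compression-onset detection, and performs solids-flux analyses.
    Includes floc morphometry (two-, three-dimensional and boundary
    fractal dimensions from images or measurement tables), seeded
    synthetic-data generators for every model family, CSV/JSON/PGM
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
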