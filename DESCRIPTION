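Package: cosolvr
Title: Restraint Generation and Probe-Map Analysis for Cosolvent Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates PLUMED lower-wall restraint scripts that prevent
    lipophilic probe aggregation in cosolvent molecular dynamics
    simulations, and implements the accompanying trajectory analyses:
    radial distribution functions under periodic boundary conditions,
    aggregation and ion-pair fraction statistics, probe-atom density
    grids and their grid free energy transform with OpenDX export.
    Includes a synthetic cosolvent box and trajectory builder and a toy
    Brownian-dynamics surrogate so the full workflow can be exercised
    and tested without a molecular dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
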