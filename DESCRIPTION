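Package: pumpflow
Title: Coupled Proboscis-Sucking Pump Fluid Mechanics for Fluid-Feeding Insects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Lubrication (Hele-Shaw) model of the insect sucking pump coupled
    to Hagen-Poiseuille flow in the proboscis food canal. Solves the mixed
    Dirichlet-Neumann Laplace problem for the chamber correction pressure on
    adaptively refined triangular meshes, computes chamber shape constants,
    plunger forces and impulse-height relations, and classifies species into
    proboscis-limited versus pump-limited energy-dissipation regimes from
    morphometric data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
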