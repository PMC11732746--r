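Package: mscflux
Title: Marine Snow Catcher Particle Flux Partitioning and Attenuation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning marine snow catcher (MSC) fraction
    concentrations into suspended, slow-sinking and fast-sinking particle
    pools, converting pools to sinking fluxes under configurable bulk
    sinking velocities with first-order uncertainty propagation, computing
    BSi:POC export stoichiometry, fitting Martin's power-law flux
    attenuation coefficients (b values) with pooling and sinking-velocity
    sensitivity analyses, and projecting fluxes and molar ratios below the
    deepest measurement. Includes a forward simulator of MSC campaigns
    with known truth so the whole measurement-to-inference chain can be
    verified without cruise data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
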