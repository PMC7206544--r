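Package: trxlsim
Title: Signal and Noise Simulation for Time-Resolved X-Ray Solution Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates the four components of a time-resolved X-ray
    solution scattering (TRXL/TRXSS) difference signal for a photochemical
    reaction in solution: the solute-only term from the Debye equation, the
    solute-solvent cage term from a hard-sphere pair-distribution
    approximation, the solvent heating term from pump-energy deposition, and
    the expected photon shot noise scaled from a reference solvent
    measurement. Assembles time-delay series under a first-order kinetic
    scheme and reports per-delay signal-to-noise for beam-time planning at
    synchrotrons and X-ray free-electron lasers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
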