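Package: tmfret
Title: Time-Resolved Transition Metal Ion FRET Analysis of TCSPC Decays
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconvolution fitting of time-correlated single photon counting
    (TCSPC) fluorescence decays with FRET models over Gaussian donor-acceptor
    distance distributions, including a two-acceptor intersubunit extension for
    homotetrameric channels. Provides global multi-condition chi-square fitting
    with parameter sharing, chi-square profile and surface identifiability
    analysis, conversion of fitted state fractions into two-state Boltzmann free
    energies, ligand-depletion dose-response fitting, and a synthetic TCSPC data
    generator so every pipeline stage is testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
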