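Package: polyeos
Title: Molecular Equations of State for Polyelectrolyte Solutions and
    Complex Coacervation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical statistical-mechanical equations of state for
    solutions of fully charged polyanions and polycations in a neutral
    monomeric solvent, treated as restricted primitive-model hard-sphere
    chains.  Implements two closed-form electrostatic free energies on top
    of the Baxter-Chiew hard-sphere-chain reference: the Blum-Stell route
    (mean spherical approximation plus a cavity-function connectivity
    correction) and the Wertheim multi-density Ornstein-Zernike route, as
    well as the classic Debye-Hueckel limiting law for comparison.  On top
    of the free energies the package computes pressures, chemical
    potentials and Gibbs free-energy densities in reduced units, solves
    liquid-liquid (complex-coacervation) two-phase equilibria at fixed
    reduced pressure, locates critical points, and extracts critical
    exponents by log-log regression near the critical point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
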