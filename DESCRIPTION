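Package: eimsim
Title: Electron-Ionization Mass Spectra from Molecular-Dynamics Fragmentation Cascades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates 70 eV electron-ionization mass spectra by the
    three-stage stochastic protocol used in quantum-chemistry-driven EI-MS
    prediction: thermal equilibration and conformer sampling of the neutral
    molecule, stochastic sampling of the internal excess energy deposited by
    the impacting electron with molecular-orbital-resolved velocity scaling,
    and hot-ion production runs in which fragmentation cascades are followed
    and the single positive charge is partitioned statistically among
    fragments by a Boltzmann weight over their vertical ionization
    potentials.  The electronic-structure backend is pluggable; a reactive
    Morse-type surrogate potential, a configurable mock molecular-orbital
    provider and a table-driven ionization-potential provider ship with the
    package so the full protocol is testable at desk scale.  Includes
    isotope-pattern convolution, MSP and JCAMP-DX spectrum I/O, spectral
    cosine similarity and analytically constructed fixture molecules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    parallel,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
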