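Package: voltsensor
Title: Voltage-Sensor Domain Analysis: Gating Charge, Helix Geometry,
    Accessibility, Free-Energy Cycles and Electrophysiology Fits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for studies of hyperpolarization-activated
    voltage sensors in ion channels such as HCN1. Implements the
    coupling-function decomposition of the gating charge from electrostatic
    potential grids, per-residue helicity and helix-bend geometry,
    Shrake-Rupley solvent accessible surface area at the MTSET probe radius,
    Bennett acceptance ratio (BAR) free-energy estimation with alchemical
    thermodynamic cycles, sum-of-two-Boltzmann open-probability fitting with
    gating polarity indices and residue-propensity correlations, MTSET
    modification kinetics, and entropy-scaled sequence-logo statistics.
    Ships deterministic synthetic generators (ideal and hinged helices,
    planar-capacitor potential grids, Crooks-consistent work samples, noisy
    Po-V curves, modification time courses, alignments with controlled
    conservation) so that every analysis stage is testable against known
    ground truth without trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
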