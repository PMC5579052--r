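Package: qcewater
Title: Quantum Cluster Equilibrium Thermodynamics and the Ionic Product of Water
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantum Cluster Equilibrium (QCE) modelling of a one-component
    molecular liquid described as a chemical equilibrium among rigid-rotor
    harmonic-oscillator clusters, extended with net-neutral hydronium/hydroxide
    ion-pair clusters so that the temperature-dependent ionic product Kw of
    water can be predicted from cluster-level quantum-chemistry data. Provides
    cluster-set input/output and validation, a synthetic cluster-set generator,
    grid-based van der Waals cluster volumes with Bondi radii, closed-form
    partition functions, a self-consistent population/volume solver with
    mean-field attraction and exclusion-volume corrections, isobar sweeps with
    phase selection and boiling-point detection, calibration of the two
    empirical parameters against a reference density and boiling temperature,
    and Eyring-type kinetic utilities for reaction free-energy profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
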