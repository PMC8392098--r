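Package: glycodpd
Title: Dissipative Particle Dynamics of Interacting Glycocalyx Brushes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mesoscale simulation and analysis of endothelial and red-blood-cell
    glycocalyx layers interacting through near-field flow. Implements a
    dissipative particle dynamics (DPD) engine in reduced units (soft pairwise
    conservative, dissipative and random forces with a pair-symmetric
    counter-based thermostat, harmonic bonds, harmonic bending, soft repulsive
    walls, Groot-Warren modified velocity-Verlet integration), builders for
    tethered and driven bead-spring chain arrays in explicit solvent, run
    protocols with timed events (chain release, activation pulses), text
    trajectory interchange (XYZ, LAMMPS dump), and tidy analysis of chain
    deformation (deflection, windowed RMSD, tip-interface splines), binned
    near-field flow (orientation statistics, Kolmogorov-Smirnov comparisons,
    shear profiles, solvent viscosity calibration, lifting force) and
    rigid-body red-blood-cell propulsion estimates with physical unit mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
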