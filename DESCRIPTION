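Package: cleftforce
Title: Domain Cleft Geometry, Contact Occupancy, Electrostatic Forces and
    MM/PBSA Energetics for Kinase Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-simulation analysis of two-domain (kinase) systems from
    multi-model PDB trajectories: mass-center cleft-size series with windowed
    statistics, Kabsch RMSD stability checks and rigid domain-separation
    protocols; salt-bridge and hydrogen-bond detection with per-pair
    occupancy across frames; screened-Coulomb inter-selection electrostatic
    forces decomposed into binding and sliding components along the
    mass-center axis, with a finite-difference linearized Poisson-Boltzmann
    solver for potentials and polar solvation; and single-trajectory MM/PBSA
    binding free energies combining Coulomb, Lennard-Jones, Poisson-Boltzmann
    polar and SASA-linear nonpolar terms. Includes deterministic synthetic
    structure generators with closed-form oracles for every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
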