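Package: steermd
Title: Steered Cofactor-Association Simulation and Active-Site Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Desk-scale analysis pipeline for steered molecular dynamics
    studies of methyl-donor cofactor association in SET-domain lysine
    methyltransferases. Provides multi-model PDB and multi-frame XYZ
    trajectory input/output with a small atom-selection language, geometric
    detection of SN2 transition-state-like cofactor docking events and
    success counting across replicate ensembles, Kabsch superposition and
    docked-pose RMSD, grid-based active-site pocket volumetrics with
    inclusion spheres, receptor-proximity pruning, convex-hull exclusion and
    contiguity filtering, heavy-atom residue contact occupancy analysis, the
    accompanying equal-variance t-test and binomial tail statistics, a
    seeded overdamped Langevin toy simulator for coarse receptor-ligand
    association, and synthetic-structure generators with analytic ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
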