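Package: cgfold
Title: Coarse-Grained Fragment-Assembly and Memetic Differential Evolution
    for Protein Structure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ab initio protein structure prediction at coarse-grained
    resolution. Conformations are encoded as per-residue backbone dihedral
    angles (omega, phi, psi) and realised in three dimensions by ideal-geometry
    forward kinematics with one side-chain pseudo-atom per residue. The package
    implements a four-stage fragment-assembly Metropolis Monte Carlo baseline
    protocol, a memetic differential-evolution search (HybridDE) that refines
    population and trial solutions by fragment insertion across a three-stage
    fitness schedule, and a crowding-niching variant (CrowdingDE) that
    preserves structurally distinct low-energy conformations. Includes
    3-mer/9-mer fragment-library construction from source structures,
    a staged surrogate energy model, Kabsch superposition and CA-RMSD,
    decoy-set energy-versus-RMSD analysis, and synthetic toy-problem
    generators used as a self-contained test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
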