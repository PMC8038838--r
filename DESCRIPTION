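Package: memtraj
Title: Membrane-Protein Molecular Dynamics Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of molecular dynamics trajectories of membrane
    proteins: per-residue alpha-helicity from i to i+4 backbone
    hydrogen-bond geometry, proximity of water, lipid tails, ions and
    ligands to protein residues under periodic boundary conditions,
    binding-event and residence-time statistics, RMSD time series with
    equilibration diagnostics, and HOLE-style pore-radius profiles with
    water-channel span detection. Includes a synthetic-trajectory
    generator (ideal helices, two-state Markov contact processes,
    helix-bundle pores) with analytically known ground truth, so every
    statistic can be validated without external simulation data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
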