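Package: peprefine
Title: Post-Docking Molecular Dynamics Refinement Analysis for
    Peptide-Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating and preparing molecular dynamics (MD)
    refinement of docked peptide-protein complexes, with a focus on
    flexible histone-tail peptides bound to reader domains. Provides
    heavy-atom RMSD with target C-alpha Kabsch superposition, refinement
    improvement (delta-RMSD) and residence-frequency metrics over
    snapshot trajectories, interface hydration editing and water-position
    match scoring, per-residue target-ligand interaction energies
    (Lennard-Jones plus Coulomb with a sigmoidal distance-dependent
    dielectric and Gasteiger-Marsili partial charges), and generation of
    six simulated-annealing MD protocol parameter sets in GROMACS mdp
    dialect. A deterministic synthetic-structure generator makes every
    metric testable without running MD.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
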