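Package: sh3tools
Title: SH3 Domain Polyproline Ligand Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing SH3 domain recognition of
    lysine-anchored class II polyproline ligands: position-frequency-matrix
    consensus construction and log-odds motif scanning of peptide libraries
    and proteomes, multi-model NMR ensemble interface analysis (hydrogen
    bond, salt bridge and nonpolar contact occupancies, binding-pocket
    assignment, backbone RMSD, relative chemical shift perturbations),
    per-residue generalized-Born/surface-area interaction-energy
    decomposition, one-site isothermal titration calorimetry and
    four-parameter logistic dose-response fitting with replicate pooling,
    and seeded synthetic-data generators with machine-readable truth
    tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
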