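Package: ppiscreen
Title: Structure-Based Virtual Screening Cascade for Protein-Protein
    Interface Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering small-molecule inhibitors of
    protein-protein interactions, modelled on the Aurora-A/TPX2 kinase
    activator complex. Implements interface hot-spot scoring from
    evolutionary conservation and an alanine-scan contact surrogate,
    protein-based pharmacophore construction with excluded volumes and
    directional projections, conformer enumeration with a pluggable
    minimizer contract, pharmacophore matching in aligned and absolute
    modes, a consensus-docking post-filter over multiple engine adapters
    (z-score selection, symmetry-aware pose RMSD, fingerprint
    clustering), and surface plasmon resonance analysis (stepwise
    FastStep injection simulation, Scatchard and nonlinear dissociation
    constant fitting, competitive-binding IC50 estimation). A synthetic
    data module generates toy receptor-peptide complexes, active/decoy
    ligand libraries, mock docking output and noisy sensorgrams with
    recorded ground truth, so the full cascade is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
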