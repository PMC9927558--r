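Package: grank
Title: Equivariant Graph Neural Network Scoring of Protein-Protein Docking Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores and ranks candidate protein-protein docking models with a
    rotation-, translation- and reflection-invariant geometric vector
    perceptron graph neural network (GVP-GNN) trained to regress the fraction
    of native contacts (f-nat). Builds atom-level interface graphs from PDB
    coordinates, computes CAPRI quality labels (f-nat, interface RMSD, ligand
    RMSD, quality class), trains fold ensembles on CPU, evaluates per-complex
    ranking quality (ROC-AUC, PR-AUC, hit rate, success rate), and ships a
    rigid-body synthetic decoy generator so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
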