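Package: gvpgo
Title: Protein Function Prediction from Predicted Structures with
    Geometric Vector Perceptrons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts Gene Ontology (GO) terms for proteins from
    AlphaFold-style predicted tertiary structures and per-residue sequence
    embeddings.  Implements geometric featurization of backbone models
    (k-nearest-neighbour graphs, edge/orientation/side-chain vectors,
    backbone dihedrals, canonical local frames, pLDDT confidence masking),
    a rotation-equivariant geometric vector perceptron graph encoder
    coupled to a GO-query transformer decoder for multi-label
    classification, the full weighted binary cross-entropy training recipe
    with Adam, GO ontology machinery (OBO parsing, annotation and
    prediction propagation, information content, candidate-term
    selection), the CAFA protein-centric (Fmax, Smin, AUPR) and
    term-centric (AUROC) evaluation suite, Naive and BLAST-transfer
    baselines, and a synthetic-data module that builds backbones with
    exactly controlled torsions so every component is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
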