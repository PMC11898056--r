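Package: stabnet
Title: Sequence- and Structure-Aware Protein Thermostability Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein thermostability (five-class organism-level
    thermostability categories, binary hot/cold, or melting temperature in
    degrees Celsius) from precomputed protein-language-model per-residue
    embeddings and residue-residue contact maps. A multilayer perceptron
    encodes per-residue sequence features, a graph convolutional network with
    symmetric adjacency normalization encodes contact-map structure, a
    residue-type-guided triplet contrastive loss ties the two representations
    together, and grouped self-attention pooling aggregates residues into a
    protein-level embedding feeding classification or regression heads. Ships
    a synthetic-data generator with controllable thermostability signal, a
    seeded Adam training loop with best-epoch selection, an evaluation suite
    (accuracy, per-class precision, macro one-vs-rest ROC and AUC, Pearson,
    Spearman, R-squared, RMSE), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
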