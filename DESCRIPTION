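Package: pbip
Title: Strain-Level Phage-Bacterium Interaction Prediction from Protein
    Sequence Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts phage-bacterium interactions at the bacterial strain
    level from protein sequences alone.  Proteomes are embedded with a
    multiplicative-LSTM protein representation model and mean-pooled to
    organism vectors; the imbalanced training set is rebalanced by SMOTE
    interpolation in the embedding space; and a convolutional / bidirectional
    GRU / attention network trained with AMSGrad scores each phage-bacterium
    pair.  Includes the full evaluation protocol for imbalanced interaction
    matrices (MCC, AUC, AUPR, stratified cross-validation, imbalance-ratio
    case studies, MinHash k-mer similarity auditing and leakage filtering)
    and a planted-motif synthetic data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
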