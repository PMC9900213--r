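Package: kinasite
Title: Kinase-Specific Phosphosite Prediction with a Transformer Encoder
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A workbench for kinase-specific phosphorylation-site prediction
    from unaligned sequence. Curates positive, hard-negative and easy-negative
    peptide pools from kinase-specific phosphosite tables, assembles 11-mer
    peptide and kinase-domain pairs, and trains a small transformer encoder
    with masked-language-model pre-training followed by focal-loss fine-tuning
    of a center-residue classification head. Includes protein-specific training
    augmentations (positive resampling, domain-boundary shifting, kinase
    masking), stratified evaluation (AUC-ROC, AUC-PRC, false-positive rate on
    easy negatives), attention and embedding interpretability, and a synthetic
    kinome generator with planted substrate-specificity grammars so the whole
    pipeline runs at desk scale without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    withr,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS
Config/testthat/edition: 3
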