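Package: editnet
Title: Hierarchical Neural-Network Ensembles for Calling RNA Editing Sites
    from Sequence Context
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies candidate single-nucleotide variants from RNA-seq into
    RNA editing sites, genomic SNPs, or other artifacts using only the one-hot
    encoded reference sequence window centred on each candidate. Implements a
    four-level ensemble of small feed-forward softmax networks (individual net,
    bagging-balanced 20-member ensemble, two-scale module, multi-module
    component, and a final separate+pooled average), a full evaluation suite
    (confusion metrics, ROC/PR AUC, A-to-I ratio, equal-error-rate FDR,
    reproducibility overlap, homologous ratio), per-position importance
    scoring, and a seeded synthetic-data generator that plants the ADAR
    neighbour-preference motif so the whole pipeline is trainable and testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    pROC,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
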