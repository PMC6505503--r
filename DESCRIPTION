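Package: immunosig
Title: Peptide Microarray Immunosignature Discovery, Validation and Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for deriving candidate peptide signatures
    from high-dimensional peptide-microarray antibody-binding data in a
    case-control setting. Provides a synthetic-data generator with planted
    signature peptides, technical replicates, batch structure and 16-bit
    saturation; preprocessing (control-peptide averaging, replicate outlier
    testing, replicate merging, median-centred log2 normalisation); six
    feature selectors (sparse PCA, sparse independent PCA, gene shaving with
    a permutation gap statistic, empirical-Bayes moderated t, random-forest
    Gini importance, and elastic-net frequency selection); set-algebra
    construction of candidate signatures from method panels; signature
    scoring with Mann-Whitney AUC validation, PC1-weight AUC, and blinded
    PCA/hierarchical clustering views; and per-peptide multi-cohort Welch-t
    signature refinement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    randomForest,
    mixOmics,
    withr
Config/testthat/edition: 3
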