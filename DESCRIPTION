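Package: lpihn
Title: Predicting lncRNA-Protein Interactions by Random Walk with Restart
    on a Heterogeneous Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts long noncoding RNA (lncRNA) binding proteins by
    network propagation. A heterogeneous network is assembled from an
    lncRNA expression-similarity layer (absolute Pearson correlation of
    expression profiles), a symmetrically normalized weighted
    protein-protein interaction layer, and known lncRNA-protein
    interactions as cross-layer edges. A random walk with restart on the
    block transition matrix scores candidate proteins for a query lncRNA.
    Includes a leave-one-out cross-validation harness with ROC/AUC,
    sensitivity at fixed specificity, precision-recall at k, fold
    enrichment and percentile-retrieval metrics, a randomized-seed
    baseline, a protein-layer-only random walk baseline, and a synthetic
    planted-structure data generator for end-to-end testing without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    Matrix,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
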