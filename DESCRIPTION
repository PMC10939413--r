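Package: aggcoex
Title: Aggregated Gene Coexpression Networks and Guilt-by-Association
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds condition-independent gene coexpression networks from
    RNA-seq count matrices using highest-reciprocal-rank (HRR) scoring and
    study-aggregated co-occurrence (COO) ranking, evaluates them by
    guilt-by-association neighbor-voting AUROC against functional annotation
    collections, and mines gene-centered subnetworks with hypergeometric
    enrichment. Includes a synthetic multi-study count-data generator with
    planted coexpression modules for end-to-end testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    fgsea,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
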