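Package: hglda
Title: Hypergeometric Inference of lncRNA-Disease Associations and
    miRNA-Based lncRNA Functional Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts long non-coding RNA (lncRNA) to disease associations by
    testing, for every lncRNA-disease pair, whether the two share significantly
    many common microRNA (miRNA) partners (one-sided hypergeometric tail test
    with Benjamini-Hochberg false discovery rate control), without requiring
    any known lncRNA-disease associations.  Also computes large-scale lncRNA
    functional similarity by cascading MeSH-DAG disease semantic similarity
    through miRNA-disease associations and lncRNA-miRNA interactions
    (best-match-average group similarity), and evaluates predictions with a
    leave-one-out ranking protocol (ROC curve and AUC).  Includes a seeded
    synthetic-fixture generator with planted shared-neighbour enrichment and
    brute-force reference oracles so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
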