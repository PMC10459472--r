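Package: coexflow
Title: Count-Matrix Filtering, Differential Expression, Co-Expression
    Clustering and Hub Gene Discovery for Staged RNA-Seq Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated workflow from a gene-by-sample read-count table to
    candidate hub genes for multi-group, ordered (time-course) RNA-seq
    designs. Covers CPM-based reliability filtering, TMM and CTF
    normalization, dispersion (BCV) assessment, mean-variance precision
    weights with moderated testing under both empirical-Bayes and
    fold-change-threshold (treat-style) schemes, ubiquitous-DEG extraction,
    co-expression clustering by agglomerative hierarchical clustering,
    k-means with a validity-index vote for the number of clusters, and
    Gaussian-mixture model selection by BIC, Pearson correlation networks
    with significance-filtered edges, node centralities including the
    Kleinberg hub score, community detection, and rule-based hub gene
    selection. Includes a negative-binomial simulator with planted
    differentially expressed genes and correlated hub modules so every
    stage can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    edgeR,
    limma,
    cluster,
    mclust,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
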