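Package: polypnet
Title: Cascaded Co-Expression and Network Clustering Analysis for
    Normal-Colon Versus Adenomatous-Polyp Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cascaded network-analysis pipeline that takes multi-batch,
    probe-level log2 expression cohorts (normal colon versus adenomatous
    polyp) to ranked biomarker gene submodules. Stages: probe-to-gene
    aggregation and empirical-Bayes batch correction; weighted gene
    co-expression module detection (soft threshold by the scale-free
    criterion, topological overlap, eigengenes, module-trait correlation);
    mapping of phenotype-linked modules onto a tissue-specific weighted
    functional interaction network; graph clustering by Markov clustering,
    greedy modularity and spectral clustering; internal (modularity,
    silhouette) and biological (biological homogeneity index, Wang semantic
    similarity) cluster scoring; differential-expression and
    over-representation filtering; and independent-cohort validation with
    compound action-type filtering. A seeded synthetic-data generator with
    planted modules, batch effects, network communities and an annotation
    DAG makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    sva,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
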