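Package: rbpAge
Title: Age and Sex Association Screening of RNA-Binding Protein
    Expression with Interaction-Network Centrality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Screens gene expression in liver cohorts for association
    with age and sex using per-gene analysis of covariance with
    Benjamini-Hochberg false discovery control and Spearman trend
    direction, merges calls across cohorts into a non-redundant set,
    and contrasts the protein-protein interaction subnetwork of
    associated genes against an ensemble of edge-subsampled random
    networks using degree, betweenness, closeness and clustering
    coefficient centralities. Includes microarray preprocessing
    (normal-plus-exponential background correction and quantile
    normalization), cross-species trend concordance with
    hypergeometric enrichment, delta-delta-Ct fold-change arithmetic,
    and a synthetic-data generator with ground-truth labels so the
    whole pipeline runs and is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
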