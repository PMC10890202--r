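Package: scRankCompare
Title: Rank-Based Cross-Cohort Comparison of Single-Cell RNA-Seq Tumor Datasets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing two single-cell RNA-seq tumor
    cohorts (for example primary liver cancer versus colorectal liver
    metastases) without cross-dataset integration. Provides quality-control
    filtering, library-size normalization, highly-variable-gene selection,
    PCA and graph-based clustering per dataset; ensemble cell-type annotation
    combining a running-sum enrichment score and a hypergeometric
    marker-overlap score with an AUC-based activity tie-break; a rank-based
    differential-expression test in which per-cell descending expression
    ranks (zeros unified to the bottom rank) are compared between conditions
    by a rank-space fold change and t statistic; a cluster-label permutation
    test for ligand-receptor communication; a per-cell rank-weighted pathway
    activity score with a Pearson correlation screen for proliferation
    driver genes; hypergeometric over-representation analysis against GMT
    collections; and a negative-binomial synthetic-cohort generator with
    planted ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
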