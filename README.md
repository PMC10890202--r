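# scRankCompare

Rank-based comparison of two single-cell RNA-seq tumor cohorts — for
example primary liver cancer versus colorectal liver metastases — without
cross-dataset integration. The package is aimed at analysts who have
several 10x-style count matrices per condition, collected by different
laboratories, and who need per-cell-type differential expression,
cell–cell communication and proliferation-driver results that are robust
to dataset-level distortions of the expression scale.

## The core statistic

Batch-correction methods can erase real biology or promote batch structure
into signal. `scRankCompare` instead compares **within-cell expression
ranks**, which are invariant to any strictly increasing per-dataset
transform. For one cell type shared by both cohorts, each dataset
contributes its top 5000 genes by mean expression; over the union of m
genes, each cell's expression is converted to descending ranks (highest
expression = 1, ties midranked) and every zero-expression gene is unified
to rank m. With mean ranks meanXᵢ (nₓ metastatic cells) and meanYᵢ (n_y
primary cells) and sᵢ the standard deviation of gene i's ranks over all
cells:

    FCᵢ = meanXᵢ / meanYᵢ
    tᵢ  = (meanXᵢ − meanYᵢ) / (sᵢ · √(1/nₓ + 1/n_y))

with two-sided p-values on nₓ + n_y − 2 df and BH adjustment. Since rank 1
is the highest expression, FC < 0.8 (q < 0.05) means up-regulated in the
metastatic cohort, FC > 1.25 down-regulated.

Around this sit the supporting stages: QC and per-dataset Leiden
clustering; ensemble cell-type annotation (running-sum enrichment score +
hypergeometric marker overlap, AUCell-style activity as tie-break); a
cluster-label permutation test for ligand–receptor communication; a
per-cell rank-weighted proliferation score with a Pearson driver screen
(r > 0.3, p < 0.05); and hypergeometric over-representation analysis. A
negative-binomial synthetic-cohort generator with planted ground truth
makes every stage testable offline. The methods vignette
(`vignettes/methods.Rmd`) documents each model and its assumptions.

## Worked example

```r
library(scRankCompare)

# a synthetic two-cohort study: 2 datasets per condition, 4 cell types,
# planted DE / interactions / drivers with truth tables
dir.create("cohort")
co <- simulateCohort(defaultSimConfig(seed = 5, cellsPerDataset = 1000))
writeCohort(co, "cohort")

cfg <- runConfig(manifest    = "cohort/manifest.tsv",
                 markersGmt  = "cohort/markers.gmt",
                 pathwaysGmt = "cohort/pathways.gmt",
                 termsGmt    = "cohort/terms.gmt",
                 lrPairs     = "cohort/lr_pairs.tsv",
                 outDir      = "cohort/run", seed = 7,
                 qc = qcThresholds(minGenesPerCell = 100))
res <- runAll(cfg)
res$deCounts
```

On this cohort the run prints (stage log abridged):

```
run-all: 4 datasets, seed 7
qc[metastatic_1]: 1000x1000 -> 1000x1000 (genes removed: 0, cells removed: 0)
cluster[metastatic_1]: 1000 cells, 1000 HVGs, 30 PCs -> 4 clusters (resolution 0.8, k 20, ...)
annotate[metastatic_1]: 4 clusters; 4 agreement, 0 tie-break
...
rankde[Tcell]: m = 1000 union genes, nx = 717, ny = 703
        type up_in_metastatic down_in_metastatic
1      Bcell                1                  0
2 Hepatocyte                0                  0
3 Macrophage                0                  0
4      Tcell               10                 10
```

All 20 DE genes planted in T cells (10 per direction) are recovered with
the correct direction, alongside one false call among the 3000 tests in
the other shared types. The
run directory contains per-stage TSVs (clusters, annotations, full
DE tables, interaction tests, pathway scores, driver screens, ORA tables)
and five summary tables: cell-type proportions per cohort, up/down DE
counts per type, per-type interaction shares, driver counts, and a
markdown digest.

A thin command-line wrapper ships in `inst/scripts/sc-rank-compare`
(`simulate` and `run-all` subcommands) for shell use; every stage is also
an exported function (`qcFilter`, `embedCluster`, `ensembleAnnotate`,
`buildRankMatrix`, `rankDeTest`, `interactionTest`, `ssScore`,
`driverScreen`, `ora`).

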