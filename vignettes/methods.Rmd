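---
title: "Methods: rank-based cross-cohort comparison of single-cell tumor datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based cross-cohort comparison of single-cell tumor datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Comparing tumor scRNA-seq cohorts collected by different laboratories — for
example primary liver cancer against colorectal-origin liver metastases —
runs into batch effects that are confounded with the biological contrast of
interest. Integration methods remove batch structure but can also remove or
fabricate biology. `scRankCompare` takes the alternative route: clustering
and annotation run **per dataset**, and the cross-cohort comparison is
carried entirely by **within-cell rank statistics**, which are invariant to
any per-dataset monotone distortion of the expression scale.

## Pipeline and models

### QC, normalization, clustering

Genes detected in fewer than 3 cells are removed, then cells with fewer
than 200 expressed genes, then cells whose mitochondrial (`MT-`), ribosomal
(`RPS`/`RPL`) or hemoglobin (`HB`, excluding `HBEGF`) count fractions
exceed 0.2 / 0.5 / 0.05. The filters are applied once, gene filter first,
and are idempotent. The family prefixes are the community convention for
human gene symbols and are configurable; the fraction caps are defaults we
had to fix for reproducibility, since a per-dataset "look at the
distribution" rule is not an algorithm. Counts are scaled per cell to a
10,000-count library and `log1p`-transformed. Highly variable genes are
ranked by a binned standardized variance (variance z-scored among genes of
similar mean, 20 bins; constants rank last, ties break by name). Clustering
scales the HVG submatrix (clipped at ±10 to bound outlier leverage), takes
30 PCs, builds a k = 20 nearest-neighbor graph and runs Leiden community
detection (modularity objective) at resolution 0.8 under a fixed seed. The
resolution and k are exposed configuration, not claims about any external
study.

We deliberately do not integrate datasets (no Harmony-style correction):
cross-dataset comparability is delegated to the rank statistics below, and
clustering quality is only needed within a dataset.

### Ensemble annotation

Per cluster, markers are genes with BH-adjusted rank-sum p < 0.05 and
log-fold change > 0.25 versus all other cells (the de-facto single-cell
standard; the rank-sum test uses the normal approximation with tie
correction). Two annotators then score candidate cell types from
user-supplied GMT signatures:

* **Enrichment score**: a weighted Kolmogorov–Smirnov running sum over the
  cluster's full logFC-ranked gene list (weight = |logFC|, exponent 1),
  normalized to an NES by the mean |ES| of same-signed gene-label
  permutations (1000 by default). Highest NES wins.
* **Marker overlap**: hypergeometric upper-tail p of the overlap between
  the cluster's marker set and each signature, with all of the dataset's
  genes as universe; smallest p wins (ties: larger overlap, then name).
  This is a fully specified stand-in for literature-evidence annotators
  whose curated databases cannot be redistributed.

When the two disagree, an AUCell-style activity decides: per cell, genes
are ranked by expression (ties by name) and the area under the recovery
curve of signature members within the top 5% of the ranking, normalized to
its maximum, is averaged over the cluster's cells for both candidates; the
higher mean activity wins, an exact tie falls back to the enrichment-score
call (it is the first-listed annotator). If only one annotator can produce
a call it stands; if neither can, the cluster is `unassigned`. Mean (not
median) is our aggregation choice for cluster activity.

### Rank-based differential expression

For one shared cell type: each dataset contributes its top 5000 genes by
mean normalized expression over that type's cells; the union of these lists
(m genes, name-sorted) forms the gene axis. Genes absent from a dataset's
list count as expression 0 there. Each cell's column is converted to
descending ranks — highest expression is rank 1, equal nonzero values share
their midrank, and **every zero-expression gene is unified to rank m**, so
sparsity has one well-defined representation. For gene i with mean rank
`meanXi` in nx metastatic cells and `meanYi` in ny primary cells, and si
the sample standard deviation of its ranks over all n = nx + ny cells:

FC = meanXi / meanYi,  t = (meanXi − meanYi) / (si · sqrt(1/nx + 1/ny))

with two-sided p on nx + ny − 2 degrees of freedom and BH adjustment over
the m genes (`adjust = FALSE` restores unadjusted screening). Because rank
1 is the highest expression, FC < 0.8 with q < 0.05 is called
`up_in_metastatic`, FC > 1.25 `down_in_metastatic`. The default denominator
is the standard pooled two-sample form; a variant without the square root,
`si · (1/nx + 1/ny)`, is kept behind `rawDenominator = TRUE` for
comparability with implementations that write the statistic that way. si is
pooled over all n cells (single-si form), with the (n−1) denominator.

Key property: multiplying any dataset's expression block by a positive
scalar — or applying any strictly increasing per-cell transform — leaves
the rank matrix bit-identical. This is the method's answer to batch
effects, and the test suite asserts it directly. A per-(dataset, gene)
batch effect is *not* removed by ranking; the synthetic null calibration
quantifies how much of it the test tolerates.

### Ligand–receptor crosstalk

For each (ligand, receptor) pair and ordered (sender, receiver) type pair,
the score is the mean of the ligand's mean normalized expression in the
sender type and the receptor's mean in the receiver type. Pairs whose
ligand (receptor) is detected in under 10% of sender (receiver) cells are
excluded rather than tested. The null shuffles type labels over all cells
(1000 permutations), p = (#{null ≥ observed} + 1)/(nPerm + 1), so p > 0
always; no cross-pair multiple-testing correction is applied, matching the
conventions of the reference tools for this analysis. On small toys
(`exact = TRUE`, ≤ 9 cells) the full permutation set is enumerated and the
p-value is the exact exceedance fraction. Multi-subunit receptor complexes
are out of scope. Per-type interaction shares count each significant
interaction for both endpoints, so shares can sum to 2.

### Proliferation scoring and the driver screen

Per-cell pathway activity is a single-sample rank-weighted running-sum
score: genes ranked by descending expression (midranks), weight
rank^−0.25, in-set steps add weight normalized to total 1, out-of-set
steps subtract uniformly, and the integrated running sum is divided by its
maximum attainable value (set at the top ranks). It is deterministic,
monotone-transform invariant, and testable against a direct summation
oracle — properties the kernel-ECDF scores of common GSVA implementations
do not offer in a self-contained form; this score is our own fully
specified construction serving the same role (a per-cell monotone activity
index). Note the statistic has a small positive offset under random set
placement (top ranks weigh more); this is irrelevant to the downstream
Pearson screen, which is location/scale invariant.

The driver screen correlates each gene with the pathway score across cells
(Pearson, two-sided p via the t transform) and selects p < 0.05 and
r > 0.3, each pathway screened separately with the union also reported; no
multiplicity correction by default (a BH option exists). Zero-variance
genes are excluded and flagged.

### Over-representation

Up/down DE lists and driver lists are tested against GMT term collections
with the exact hypergeometric upper tail, BH-corrected across terms. The
universe is all genes surviving QC in the cohort, the standard ORA choice
when the assay, not the genome, defines what could have been observed.

## The synthetic-data generator

`simulateCohort()` defines the study conditions the package is tested
under: two datasets per condition; four cell types (T cell, B cell,
hepatocyte, macrophage; proportions 0.35/0.25/0.25/0.15) with 25 markers
each boosted 8-fold; 20 DE genes at |log2FC| = 2 in T cells (half up in
each condition); three ligand–receptor pairs boosted 8-fold in their
sender/receiver types; two 20-gene proliferation pathway sets and 50
driver genes at target correlation ρ = 0.5 with a per-cell latent N(0,1)
activity. Baseline gene means are log-normal (planted genes floored at
mean 2 so structure sits on expressed genes); counts are negative binomial
(size 2) with 5% uniform dropout; each (dataset, gene) carries a log-normal
batch factor with sd 0.08 — mild residual technical variation, set during
generator design so that the generator's declared statistical properties
(marker separability, DE effect sizes, the rank test's null calibration
band, driver correlations) hold simultaneously. Driver loadings are
calibrated against the exact zero-inflated NB measurement model (local
slope and variance of `log1p` expression), so the realized correlation
tracks ρ; library-size normalization re-attenuates it slightly because the
latent activity also moves total counts.

What the generator does **not** emulate: gene-length/GC bias, doublets,
zero inflation beyond uniform dropout, trajectory or subtype structure,
and realistic marker-gene overlap between related types. Passing tests
therefore demonstrate correctness of the algorithms and their stated
invariants under a clean generative model — not performance on real
tissue.

## Numerical choices and degenerate inputs

* Ties: midranks within nonzero expression (rank DE, pathway score);
  gene-name order for the AUCell ranking and all top-k lists (exact
  determinism).
* Genes with zero rank variance get an undefined t and are reported `ns`
  with a flag; constant genes are excluded from the driver screen.
* Clustering clips standardized expression at ±10; k is reduced with a
  warning when a dataset has fewer cells than k.
* All permutation stages take explicit seeds; `runAll()` fans one global
  seed out per stage by hashing the stage name, so any stage can be re-run
  in isolation with identical results.
* Problem sizes in the test suite (up to 2500 cells per dataset for the
  end-to-end determinism check, 1000-gene panels elsewhere) are desk-scale
  choices that keep the full suite comfortably reproducible on a laptop
  while leaving every statistical property measurable.

## Known limitations

* Per-dataset clustering means cluster boundaries are not shared across
  datasets; comparability rests entirely on the annotation step.
* The rank t-test treats cells as exchangeable within a condition; with
  few datasets per condition, per-gene batch variation adds mild
  pseudoreplication that the null calibration quantifies (fractions of
  p < 0.05 around 0.06–0.08 at the default batch sd, within the asserted
  [0.02, 0.09] band).
* The marker-overlap annotator is only as good as the supplied GMT
  signatures; it does not model evidence quality tiers.
* Interaction scores use binary pairs only and a one-sided "≥" null.
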