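#' Quality-control thresholds
#'
#' Gene and cell filters applied once, gene filter first: genes expressed in
#' fewer than \code{minCellsPerGene} cells are removed, then cells with
#' fewer than \code{minGenesPerCell} expressed genes, then cells whose
#' mitochondrial / ribosomal / hemoglobin count fractions exceed the caps.
#' Gene families are detected by symbol prefix (community convention):
#' mitochondrial \code{MT-}, ribosomal \code{RPS}/\code{RPL}, hemoglobin
#' \code{HB} excluding \code{HBEGF}; all prefix rules are overridable.
#'
#' @param minCellsPerGene minimum cells a gene must be detected in (default 3).
#' @param minGenesPerCell minimum expressed genes per cell (default 200).
#' @param maxMitoFraction,maxRiboFraction,maxHbFraction per-cell caps on the
#'   family count fractions, in (0, 1].
#' @param mitoPattern,riboPattern regexes matching family gene symbols.
#' @param hbPattern,hbExclude hemoglobin regex and exact-symbol exclusions.
#' @return a \code{QCThresholds} list.
#' @export
qcThresholds <- function(minCellsPerGene = 3, minGenesPerCell = 200,
                         maxMitoFraction = 0.2, maxRiboFraction = 0.5,
                         maxHbFraction = 0.05, mitoPattern = "^MT-",
                         riboPattern = "^RP[SL]", hbPattern = "^HB",
                         hbExclude = "HBEGF") {
  stopifnot(minCellsPerGene > 0, minGenesPerCell > 0,
            maxMitoFraction > 0, maxRiboFraction > 0, maxHbFraction > 0)
  structure(list(minCellsPerGene = minCellsPerGene,
                 minGenesPerCell = minGenesPerCell,
                 maxMitoFraction = maxMitoFraction,
                 maxRiboFraction = maxRiboFraction,
                 maxHbFraction = maxHbFraction,
                 mitoPattern = mitoPattern, riboPattern = riboPattern,
                 hbPattern = hbPattern, hbExclude = hbExclude),
            class = "QCThresholds")
}

#' Quality-control filtering of a CountMatrix
#'
#' Applies the gene filter, then the cell filters, in a single pass (no
#' iteration); see [qcThresholds()] for the rules. Idempotent on its own
#' output.
#'
#' @param cm a \linkS4class{CountMatrix}.
#' @param th a \code{QCThresholds}.
#' @return the filtered \linkS4class{CountMatrix}.
#' @export
qcFilter <- function(cm, th = qcThresholds()) {
  cts <- assay(cm, "counts")
  keepGene <- Matrix::rowSums(cts > 0) >= th$minCellsPerGene
  cts <- cts[keepGene, , drop = FALSE]
  genesPerCell <- Matrix::colSums(cts > 0)
  tot <- Matrix::colSums(cts)
  frac <- function(sel) {
    s <- if (any(sel)) Matrix::colSums(cts[sel, , drop = FALSE]) else 0
    ifelse(tot > 0, s / pmax(tot, 1), 0)
  }
  gn <- rownames(cts)
  mito <- frac(grepl(th$mitoPattern, gn))
  ribo <- frac(grepl(th$riboPattern, gn))
  hb <- frac(grepl(th$hbPattern, gn) & !(gn %in% th$hbExclude))
  keepCell <- genesPerCell >= th$minGenesPerCell &
    mito <= th$maxMitoFraction & ribo <= th$maxRiboFraction &
    hb <= th$maxHbFraction
  if (!any(keepCell)) stop("empty dataset after QC")
  out <- cm[keepGene, keepCell]
  stageLog("qc[", datasetId(cm), "]: ", nrow(cm), "x", ncol(cm), " -> ",
           nrow(out), "x", ncol(out), " (genes removed: ", sum(!keepGene),
           ", cells removed: ", sum(!keepCell), ")")
  out
}

#' Library-size normalization with log transform
#'
#' Scales each cell to a fixed library size, then applies \code{log1p};
#' stores the result as the \code{"lognorm"} assay.
#'
#' @param cm a QC-passed \linkS4class{CountMatrix}.
#' @param targetSize target library size per cell (default 10000).
#' @return \code{cm} with a \code{"lognorm"} assay.
#' @export
normalizeLog <- function(cm, targetSize = 1e4) {
  cts <- assay(cm, "counts")
  lib <- Matrix::colSums(cts)
  if (any(lib == 0)) stop("zero-count cell: run qcFilter first")
  scaled <- cts %*% Matrix::Diagonal(x = targetSize / lib)
  dimnames(scaled) <- dimnames(cts)
  assay(cm, "lognorm") <- log1p(scaled)
  cm
}

#' Select highly variable genes
#'
#' Ranks genes by a standardized dispersion of their log-normalized
#' expression: per-gene variance, z-scored within 20 equal-occupancy bins of
#' the per-gene mean (so the statistic is variance relative to genes of a
#' similar expression level). Ties are broken by gene-name order; constant
#' genes rank last.
#'
#' @param cm a \linkS4class{CountMatrix} with a \code{"lognorm"} assay.
#' @param nTop number of genes to select (default 2000; all if fewer).
#' @param nBins number of mean-occupancy bins.
#' @return character vector of selected gene symbols.
#' @export
selectHvg <- function(cm, nTop = 2000, nBins = 20) {
  x <- assay(cm, "lognorm")
  mu <- Matrix::rowSums(x) / ncol(x)
  v <- Matrix::rowSums(x^2) / ncol(x) - mu^2
  v <- v * ncol(x) / max(1, ncol(x) - 1)
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = min(nBins, length(mu)), labels = FALSE)
  z <- numeric(length(v))
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(v[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (v[i] - mean(v[i])) / s
  }
  z[v == 0] <- -Inf  # constant genes rank last regardless of bin
  ord <- order(-z, rownames(x))
  rownames(x)[ord][seq_len(min(nTop, length(ord)))]
}

#' PCA embedding and graph-based clustering
#'
#' Scales the HVG submatrix of the log-normalized data to zero mean and unit
#' variance per gene (clipping standardized values at ±10 to bound outlier
#' leverage), runs PCA, builds a k-nearest-neighbor graph in PC space, and
#' partitions it with Leiden community detection (modularity objective) at
#' the given resolution. Deterministic given the seed. Cluster labels are
#' \code{0..K-1}, ordered by decreasing cluster size.
#'
#' @param cm a \linkS4class{CountMatrix} with \code{"lognorm"}.
#' @param hvg highly variable genes (default: [selectHvg()] on \code{cm}).
#' @param nPcs number of principal components (default 30, capped at the
#'   data's rank).
#' @param k neighbors for the kNN graph (default 20; reduced with a warning
#'   when fewer cells are available).
#' @param resolution Leiden resolution parameter (default 0.8).
#' @param seed RNG seed for the community detection.
#' @return \code{cm} with a \code{"PCA"} reduced dimension and a
#'   \code{cluster} column in \code{colData}.
#' @export
embedCluster <- function(cm, hvg = NULL, nPcs = 30, k = 20, resolution = 0.8,
                         seed = 1) {
  if (is.null(hvg)) hvg <- selectHvg(cm)
  x <- as.matrix(assay(cm, "lognorm")[hvg, , drop = FALSE])
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  keep <- sdv > 0
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  z[z > 10] <- 10; z[z < -10] <- -10
  nPcs <- min(nPcs, nrow(z) - 1L, ncol(z) - 1L)
  pca <- stats::prcomp(t(z), center = TRUE, scale. = FALSE, rank. = nPcs)
  emb <- pca$x
  n <- nrow(emb)
  if (n <= k) {
    warning("fewer cells than k; reducing k to ", n - 1L)
    k <- n - 1L
  }
  d2 <- as.matrix(stats::dist(emb))
  nb <- t(apply(d2, 1, function(r) order(r)[2:(k + 1L)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nb)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 n_iterations = 5)
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  cl <- unname(relabel[as.character(memb)])
  reducedDim(cm, "PCA") <- emb
  cm$cluster <- cl
  metadata(cm)$hvg <- hvg
  stageLog("cluster[", datasetId(cm), "]: ", ncol(cm), " cells, ",
           length(hvg), " HVGs, ", nPcs, " PCs -> ", length(sizes),
           " clusters (resolution ", resolution, ", k ", k, ", seed ", seed, ")")
  cm
}
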