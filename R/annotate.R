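#' Per-cluster marker genes (rank-sum test, cluster vs. rest)
#'
#' For every cluster, each gene is scored by the difference in mean
#' log-normalized expression between the cluster and all other cells
#' (\code{logFC}) and tested with a two-sided Wilcoxon rank-sum test
#' (normal approximation with tie correction), BH-adjusted per cluster.
#' Markers are genes with adjusted p < 0.05 and logFC > 0.25, sorted by
#' decreasing logFC.
#'
#' @param cm a clustered \linkS4class{CountMatrix} (see [embedCluster()]).
#' @param minLogFC,maxPadj marker thresholds.
#' @return a list, one element per cluster label, each with \code{cluster},
#'   \code{table} (all genes, ranked by decreasing logFC) and
#'   \code{markers} (the significant marker symbols).
#' @export
findClusterMarkers <- function(cm, minLogFC = 0.25, maxPadj = 0.05) {
  if (is.null(cm$cluster)) stop("no cluster labels: run embedCluster first")
  cl <- cm$cluster
  if (length(unique(cl)) < 2) stop("at least 2 clusters are required")
  x <- as.matrix(assay(cm, "lognorm"))
  n <- ncol(x)
  rk <- t(apply(x, 1, rank))  # midranks across all cells, per gene
  # tie correction term per gene: sum(t^3 - t) over tie groups
  tieTerm <- apply(x, 1, function(v) {
    tb <- table(v)
    sum(tb^3 - tb)
  })
  totalMean <- rowMeans(x)
  out <- list()
  for (lab in sort(unique(cl))) {
    inCl <- cl == lab
    n1 <- sum(inCl); n2 <- n - n1
    key <- as.character(lab)
    if (n1 < 2) {
      warning("cluster ", lab, " has fewer than 2 cells; markers undefined")
      out[[key]] <- list(cluster = lab,
                         table = data.frame(gene = character(),
                                            logFC = numeric(), p = numeric(),
                                            padj = numeric()),
                         markers = character())
      next
    }
    meanIn <- rowMeans(x[, inCl, drop = FALSE])
    logFC <- meanIn - (totalMean * n - meanIn * n1) / n2
    r1 <- rowSums(rk[, inCl, drop = FALSE])
    mu <- n1 * (n + 1) / 2
    sig2 <- n1 * n2 / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
    z <- (r1 - mu) / sqrt(pmax(sig2, .Machine$double.eps))
    p <- 2 * stats::pnorm(-abs(z))
    p[sig2 == 0] <- 1
    padj <- stats::p.adjust(p, "BH")
    ord <- order(-logFC, rownames(x))
    tab <- data.frame(gene = rownames(x)[ord], logFC = logFC[ord],
                      p = p[ord], padj = padj[ord], row.names = NULL)
    mk <- tab$gene[tab$padj < maxPadj & tab$logFC > minLogFC]
    out[[key]] <- list(cluster = lab, table = tab, markers = mk)
  }
  out
}

# Weighted KS running-sum enrichment score from in-set positions.
# pos: sorted 1-based positions of set genes in the ranked list;
# w: |score| weights aligned to the ranked list; G: list length.
# Returns the running-sum extremum with the largest magnitude.
.enrichmentScore <- function(pos, w, G) {
  s <- length(pos)
  wSet <- w[pos]
  tot <- sum(wSet)
  if (tot == 0) { wSet <- rep(1, s); tot <- s }  # degenerate all-zero weights
  missStep <- 1 / (G - s)
  hitCum <- cumsum(wSet) / tot
  afterHit <- hitCum - (pos - seq_len(s)) * missStep
  # running sum just before each hit
  beforeHit <- c(0, hitCum[-s]) - (pos - 1 - (seq_len(s) - 1)) * missStep
  cand <- c(afterHit, beforeHit)
  cand[which.max(abs(cand))]
}

#' Enrichment-score annotation of one cluster
#'
#' Ranks the cluster's full gene list by decreasing marker score (logFC) and
#' computes, for each candidate signature, a weighted Kolmogorov-Smirnov
#' running-sum enrichment score (weight = |score|, exponent 1). The
#' normalized enrichment score (NES) divides the ES by the mean |ES*| of
#' gene-label permutations whose ES* carries the same sign. The candidate
#' with the highest NES wins.
#'
#' @param markers one element of [findClusterMarkers()] output.
#' @param db candidate signatures as a \linkS4class{SignatureDB}.
#' @param nPerm number of gene-label permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return list with \code{call} (best type, \code{NA} if no signature was
#'   scorable) and \code{table} (type, nGenes, ES, NES).
#' @export
gseaAnnotate <- function(markers, db, nPerm = 1000, seed = 1) {
  tab <- markers$table
  if (!nrow(tab)) stop("empty marker table")
  G <- nrow(tab)
  w <- abs(tab$logFC)
  geneIdx <- stats::setNames(seq_len(G), tab$gene)
  set.seed(seed)
  rows <- list()
  for (ty in names(db)) {
    pos <- sort(unname(geneIdx[db[[ty]][db[[ty]] %in% names(geneIdx)]]))
    if (length(pos) < 2) {
      warning("signature '", ty, "' has fewer than 2 genes in the ranking; skipped")
      next
    }
    es <- .enrichmentScore(pos, w, G)
    perm <- vapply(seq_len(nPerm), function(i) {
      .enrichmentScore(sort(sample.int(G, length(pos))), w, G)
    }, numeric(1))
    same <- perm[sign(perm) == sign(es)]
    denom <- if (length(same)) mean(abs(same)) else mean(abs(perm))
    nes <- if (denom > 0) es / denom else 0
    rows[[ty]] <- data.frame(type = ty, nGenes = length(pos), ES = es, NES = nes)
  }
  if (!length(rows)) return(list(call = NA_character_, table = NULL))
  tab2 <- do.call(rbind, rows)
  rownames(tab2) <- NULL
  best <- tab2$type[order(-tab2$NES, tab2$type)][1]
  list(call = best, table = tab2)
}

#' Marker-overlap annotation of one cluster
#'
#' Hypergeometric upper-tail test of the overlap between the cluster's
#' marker set and each candidate signature, with the dataset's full gene
#' list as universe. The smallest p wins; ties go to the larger overlap,
#' then name order. If no signature overlaps at all, the best type is still
#' reported (p = 1) and flagged low-confidence.
#'
#' @param markers one element of [findClusterMarkers()] output.
#' @param db candidate signatures.
#' @param universe all gene symbols in the dataset.
#' @return list with \code{call}, \code{lowConfidence} flag, and
#'   \code{table} (type, k, K, n, N, p).
#' @export
overlapAnnotate <- function(markers, db, universe) {
  mk <- intersect(markers$markers, universe)
  if (!length(mk)) stop("empty marker set")
  N <- length(universe); n <- length(mk)
  rows <- lapply(names(db), function(ty) {
    sig <- intersect(db[[ty]], universe)
    k <- length(intersect(mk, sig)); K <- length(sig)
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(type = ty, k = k, K = K, n = n, N = N, p = p)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- tab$type[order(tab$p, -tab$k, tab$type)][1]
  list(call = best, lowConfidence = all(tab$k == 0), table = tab)
}

#' AUCell-style per-cell gene-set activity
#'
#' Ranks the cell's genes by decreasing expression (ties broken by gene-name
#' order) and computes the area under the recovery curve of set members
#' within the top \code{ceiling(topFraction * G)} genes, normalized by the
#' maximal attainable area. Depends only on within-cell expression ranks,
#' so it is invariant to monotone transforms of the expression vector.
#'
#' @param expr named expression vector for one cell.
#' @param geneSet character vector of set members.
#' @param topFraction fraction of the ranking forming the recovery window
#'   (default 0.05).
#' @return AUC in \code{[0, 1]}.
#' @export
aucellScore <- function(expr, geneSet, topFraction = 0.05) {
  G <- length(expr)
  present <- intersect(geneSet, names(expr))
  if (!length(present)) {
    warning("gene set entirely absent from the expression universe")
    return(0)
  }
  ord <- order(-expr, names(expr))
  rk <- stats::setNames(seq_len(G), names(expr)[ord])
  W <- ceiling(topFraction * G)
  hits <- sort(unname(rk[present]))
  inWin <- hits[hits <= W]
  raw <- sum(W - inWin + 1)
  sMax <- min(length(present), W)
  maxRaw <- sum(W - seq_len(sMax) + 1)
  raw / maxRaw
}

#' Ensemble cell-type annotation with AUC tie-break
#'
#' Runs the enrichment-score and marker-overlap annotators on every
#' cluster. When both agree, the shared call is final
#' (\code{decision_path = "agreement"}). When they disagree, the mean
#' AUCell-style activity of the two candidate signatures over the cluster's
#' cells decides (\code{"aucell_tiebreak"}); an exact tie falls back to the
#' enrichment-score call. If only one annotator produces a call it stands
#' (\code{"single"}); if neither does, the cluster is \code{"unassigned"}.
#'
#' @param cm a clustered, normalized \linkS4class{CountMatrix}.
#' @param db candidate signatures.
#' @param nPerm permutations for the NES.
#' @param seed RNG seed.
#' @param topFraction AUCell recovery-window fraction.
#' @return data.frame with one row per cluster: \code{cluster},
#'   \code{gsea_call}, \code{gsea_nes}, \code{overlap_call},
#'   \code{overlap_p}, \code{aucell_gsea}, \code{aucell_overlap},
#'   \code{final_call}, \code{decision_path}.
#' @export
ensembleAnnotate <- function(cm, db, nPerm = 1000, seed = 1,
                             topFraction = 0.05) {
  mks <- findClusterMarkers(cm)
  x <- as.matrix(assay(cm, "lognorm"))
  universe <- rownames(cm)
  rows <- list()
  for (key in names(mks)) {
    mk <- mks[[key]]
    row <- data.frame(cluster = mk$cluster, gsea_call = NA_character_,
                      gsea_nes = NA_real_, overlap_call = NA_character_,
                      overlap_p = NA_real_, aucell_gsea = NA_real_,
                      aucell_overlap = NA_real_,
                      final_call = "unassigned", decision_path = "unassigned")
    if (length(mk$markers)) {
      gs <- gseaAnnotate(mk, db, nPerm = nPerm, seed = seed)
      ov <- overlapAnnotate(mk, db, universe)
      row$gsea_call <- gs$call
      if (!is.na(gs$call))
        row$gsea_nes <- gs$table$NES[gs$table$type == gs$call]
      row$overlap_call <- ov$call
      row$overlap_p <- ov$table$p[ov$table$type == ov$call]
      if (is.na(gs$call) && is.na(ov$call)) {
        # stays unassigned
      } else if (is.na(gs$call) || is.na(ov$call)) {
        row$final_call <- if (is.na(gs$call)) ov$call else gs$call
        row$decision_path <- "single"
      } else if (identical(gs$call, ov$call)) {
        row$final_call <- gs$call
        row$decision_path <- "agreement"
      } else {
        cells <- which(cm$cluster == mk$cluster)
        aucMean <- function(type) {
          mean(vapply(cells, function(j)
            aucellScore(x[, j], db[[type]], topFraction), numeric(1)))
        }
        aG <- aucMean(gs$call); aO <- aucMean(ov$call)
        row$aucell_gsea <- aG; row$aucell_overlap <- aO
        row$final_call <- if (aO > aG) ov$call else gs$call
        row$decision_path <- "aucell_tiebreak"
      }
    } else {
      warning("cluster ", mk$cluster, " has no markers; labeled unassigned")
    }
    rows[[key]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stageLog("annotate[", datasetId(cm), "]: ", nrow(out), " clusters; ",
           sum(out$decision_path == "agreement"), " agreement, ",
           sum(out$decision_path == "aucell_tiebreak"), " tie-break")
  out
}

#' Map cluster annotations to per-cell type labels
#'
#' @param cm a clustered \linkS4class{CountMatrix}.
#' @param annotation result of [ensembleAnnotate()].
#' @return character vector of cell types, aligned to \code{colnames(cm)}.
#' @export
annotateCells <- function(cm, annotation) {
  map <- stats::setNames(annotation$final_call, annotation$cluster)
  unname(map[as.character(cm$cluster)])
}
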