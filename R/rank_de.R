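#' Top genes of one cell type in one dataset
#'
#' Genes sorted by decreasing mean normalized expression over the dataset's
#' cells of the given type; the top \code{k} (all, if fewer) form the
#' dataset's contribution to the merged gene union. Ties break by gene-name
#' order.
#'
#' @param cm a normalized \linkS4class{CountMatrix}.
#' @param cellTypes per-cell type labels aligned to \code{colnames(cm)}.
#' @param cellType the type to profile.
#' @param k number of genes to keep (default 5000).
#' @return character vector of gene symbols in mean-descending order.
#' @export
topGenesPerDataset <- function(cm, cellTypes, cellType, k = 5000) {
  sel <- which(cellTypes == cellType)
  if (!length(sel)) {
    warning("no cells of type '", cellType, "' in dataset ", datasetId(cm))
    return(character())
  }
  x <- assay(cm, "lognorm")[, sel, drop = FALSE]
  mu <- Matrix::rowSums(x) / length(sel)
  ord <- order(-mu, rownames(cm))
  rownames(cm)[ord][seq_len(min(k, length(ord)))]
}

#' Build the merged per-cell rank matrix for one cell type
#'
#' Merges per-dataset expression blocks of one cell type over the union of
#' their top-gene lists (m genes, name-sorted). A gene absent from a
#' dataset's list is treated as expression 0 in that dataset's cells. Each
#' column (cell) is then converted to descending ranks: highest expression
#' gets rank 1, equal nonzero values share their midrank, and every
#' zero-expression gene is unified to rank m. Ranking a cell depends only
#' on the ordering of its values, so any strictly increasing per-cell
#' transform — including a per-dataset positive scale factor — leaves the
#' result identical.
#'
#' @param blocks list of per-dataset contributions, each a list with
#'   \code{expr} (genes x cells normalized expression for the type's cells),
#'   \code{genes} (that dataset's top-gene list) and \code{condition}.
#' @return a \linkS4class{RankMatrix}.
#' @export
buildRankMatrix <- function(blocks) {
  conds <- vapply(blocks, `[[`, character(1), "condition")
  if (!all(VALID_CONDITIONS %in% conds))
    stop("one-sided comparison: both conditions must contribute cells")
  union <- sort(unique(unlist(lapply(blocks, `[[`, "genes"))))
  m <- length(union)
  cols <- list(); colCond <- character()
  for (b in blocks) {
    expr <- matrix(0, m, ncol(b$expr), dimnames = list(union, colnames(b$expr)))
    keep <- intersect(rownames(b$expr), intersect(b$genes, union))
    expr[keep, ] <- as.matrix(b$expr[keep, , drop = FALSE])
    cols[[length(cols) + 1L]] <- expr
    colCond <- c(colCond, rep(b$condition, ncol(expr)))
  }
  expr <- do.call(cbind, cols)
  ranks <- apply(expr, 2, function(v) {
    r <- rep.int(m, length(v))
    nz <- v > 0
    if (any(nz)) r[nz] <- rank(-v[nz], ties.method = "average")
    r
  })
  dimnames(ranks) <- dimnames(expr)
  cond <- factor(colCond, levels = c("metastatic", "primary"))
  new("RankMatrix", genes = union, ranks = ranks, condition = cond,
      nx = sum(cond == "metastatic"), ny = sum(cond == "primary"))
}

#' Rank-space differential expression test
#'
#' For each union gene, computes the mean rank in the metastatic cells
#' (\code{meanXi}) and primary cells (\code{meanYi}), the rank-space fold
#' change \code{FC = meanXi / meanYi}, and the t statistic
#' \deqn{t = (meanXi - meanYi) / (s_i \sqrt{1/n_x + 1/n_y})}
#' where \code{si} is the sample standard deviation of the gene's ranks over
#' all \code{n = nx + ny} cells. Two-sided p-values use \code{nx + ny - 2}
#' degrees of freedom and are BH-adjusted across the m genes. Because
#' rank 1 marks the highest expression, \code{FC < fcBounds[1]} with
#' \code{q < alpha} is called \code{up_in_metastatic} and
#' \code{FC > fcBounds[2]} is \code{down_in_metastatic}; everything else is
#' \code{ns}. Genes with \code{si = 0} get an undefined t and are flagged.
#'
#' @param rm a \linkS4class{RankMatrix} with at least 2 cells per condition.
#' @param fcBounds rank-ratio significance bounds (default \code{c(0.8, 1.25)}).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param adjust apply BH adjustment (\code{q = p} when \code{FALSE}).
#' @param rawDenominator use the literal denominator
#'   \code{si * (1/nx + 1/ny)} (no square root) instead of the standard
#'   pooled two-sample form.
#' @return data.frame with columns \code{gene}, \code{meanXi}, \code{meanYi},
#'   \code{si}, \code{FC}, \code{t}, \code{p}, \code{q}, \code{direction},
#'   \code{zero_sd}.
#' @export
rankDeTest <- function(rm, fcBounds = c(0.8, 1.25), alpha = 0.05,
                       adjust = TRUE, rawDenominator = FALSE) {
  nx <- rm@nx; ny <- rm@ny
  if (nx < 2 || ny < 2) stop("insufficient cells: need >= 2 per condition")
  r <- rm@ranks
  n <- nx + ny
  met <- rm@condition == "metastatic"
  meanX <- rowMeans(r[, met, drop = FALSE])
  meanY <- rowMeans(r[, !met, drop = FALSE])
  rowMean <- rowMeans(r)
  si <- sqrt(pmax(0, (rowSums(r^2) - n * rowMean^2) / (n - 1)))
  fc <- meanX / meanY
  denom <- if (rawDenominator) si * (1 / nx + 1 / ny)
           else si * sqrt(1 / nx + 1 / ny)
  t <- (meanX - meanY) / denom
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  zeroSd <- si == 0
  t[zeroSd] <- NA_real_
  p[zeroSd] <- NA_real_
  q <- if (adjust) stats::p.adjust(p, "BH") else p
  direction <- rep("ns", length(fc))
  sig <- !is.na(q) & q < alpha
  direction[sig & fc < fcBounds[1]] <- "up_in_metastatic"
  direction[sig & fc > fcBounds[2]] <- "down_in_metastatic"
  direction[zeroSd] <- "ns"
  data.frame(gene = rm@genes, meanXi = meanX, meanYi = meanY, si = si,
             FC = fc, t = t, p = p, q = q, direction = direction,
             zero_sd = zeroSd, row.names = NULL)
}

#' Cross-cohort rank DE for one annotated cell type
#'
#' Convenience wrapper: extracts each dataset's cells of the given type,
#' takes its top-gene list, builds the merged [buildRankMatrix()] and runs
#' [rankDeTest()].
#'
#' @param datasets list of normalized \linkS4class{CountMatrix} objects.
#' @param typeLabels list of per-cell type vectors, aligned to
#'   \code{datasets}.
#' @param cellType the shared cell type to compare.
#' @param topK per-dataset top-gene list size (default 5000).
#' @param ... passed to [rankDeTest()].
#' @return data.frame as from [rankDeTest()].
#' @export
rankDeForType <- function(datasets, typeLabels, cellType, topK = 5000, ...) {
  blocks <- list()
  for (i in seq_along(datasets)) {
    cm <- datasets[[i]]
    sel <- which(typeLabels[[i]] == cellType)
    if (!length(sel)) next
    top <- topGenesPerDataset(cm, typeLabels[[i]], cellType, k = topK)
    blocks[[length(blocks) + 1L]] <- list(
      expr = assay(cm, "lognorm")[, sel, drop = FALSE],
      genes = top, condition = cohortCondition(cm))
  }
  if (!length(blocks)) stop("no dataset contributes cells of type '", cellType, "'")
  rm <- buildRankMatrix(blocks)
  stageLog("rankde[", cellType, "]: m = ", nGenes(rm), " union genes, nx = ",
           rm@nx, ", ny = ", rm@ny)
  rankDeTest(rm, ...)
}
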