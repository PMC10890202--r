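# Raw rank-weighted running-sum statistic for one cell.
# rk: per-gene descending midranks; inSet: logical; alpha: weight exponent.
# Walks the ranked list, adding weight-normalized in-set steps and
# subtracting uniform out-of-set steps, and integrates the running sum.
.ssRaw <- function(rk, inSet, alpha) {
  G <- length(rk)
  S <- sum(inSet)
  ord <- order(rk)
  w <- rk[ord]^(-alpha)
  hit <- inSet[ord]
  step <- ifelse(hit, w / sum(w[hit]), -1 / (G - S))
  sum(cumsum(step))
}

#' Single-sample rank-weighted pathway activity score
#'
#' For each cell, genes are ranked by decreasing expression (midranks for
#' ties) and weighted as \code{rank^-weightExponent}, so top-ranked genes
#' dominate. A running sum accumulates the weighted in-set steps
#' (normalized to total 1) and subtracts uniform out-of-set steps; the raw
#' score integrates this running sum over the full list and is divided by
#' the maximum attainable value, reached when the set occupies the top |S|
#' ranks. The score depends only on within-cell expression ranks, so it is
#' invariant to per-cell monotone transforms, and is near 0 for a randomly
#' placed set.
#'
#' @param x normalized genes-by-cells matrix (or a vector for one cell).
#' @param geneSet pathway member symbols; at least 2 must be present in the
#'   matrix's gene universe.
#' @param weightExponent rank-weight exponent (default 0.25).
#' @return numeric vector of per-cell scores, named by cell.
#' @export
ssScore <- function(x, geneSet, weightExponent = 0.25) {
  if (is.vector(x)) x <- matrix(x, ncol = 1, dimnames = list(names(x), "cell"))
  x <- as.matrix(x)
  inSet <- rownames(x) %in% geneSet
  S <- sum(inSet)
  if (S == 0) stop("empty pathway: no set gene present in the universe")
  if (S < 2) stop("pathway needs >= 2 genes present in the universe")
  G <- nrow(x)
  # maximum attainable raw score: set at ideal top ranks 1..S
  idealRk <- seq_len(G)
  idealIn <- idealRk <= S
  maxRaw <- .ssRaw(idealRk, idealIn, weightExponent)
  scores <- apply(x, 2, function(v) {
    rk <- rank(-v, ties.method = "average")
    .ssRaw(rk, inSet, weightExponent) / maxRaw
  })
  scores
}

#' Per-cell scores for a collection of pathways
#'
#' @param cm a normalized \linkS4class{CountMatrix} (or genes-by-cells
#'   matrix).
#' @param db a \linkS4class{SignatureDB} of pathway sets.
#' @param weightExponent passed to [ssScore()].
#' @return data.frame with columns \code{barcode}, \code{pathway},
#'   \code{score}.
#' @export
pathwayScores <- function(cm, db, weightExponent = 0.25) {
  x <- if (is(cm, "CountMatrix")) as.matrix(assay(cm, "lognorm")) else as.matrix(cm)
  out <- lapply(names(db), function(nm) {
    data.frame(barcode = colnames(x), pathway = nm,
               score = unname(ssScore(x, db[[nm]], weightExponent)))
  })
  do.call(rbind, out)
}

#' Pearson screen for proliferation driver genes
#'
#' Correlates each gene's normalized expression with a per-cell pathway
#' activity score across cells. Two-sided p-values come from the t
#' transform with \code{n - 2} degrees of freedom. A gene is selected when
#' \code{p < alpha} and \code{r > rMin} (the positive screen); the returned
#' r and p also support a mirrored negative screen. Zero-variance genes are
#' excluded and flagged. Selection is invariant to affine transforms of the
#' score vector.
#'
#' @param x normalized genes-by-cells matrix.
#' @param scores per-cell pathway score, aligned to \code{colnames(x)}.
#' @param rMin correlation threshold (default 0.3).
#' @param alpha significance level (default 0.05).
#' @param adjust optionally BH-adjust the p-values before thresholding.
#' @return data.frame with columns \code{gene}, \code{r}, \code{p},
#'   \code{selected}, \code{zero_var}.
#' @export
driverScreen <- function(x, scores, rMin = 0.3, alpha = 0.05, adjust = FALSE) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 3) stop("fewer than 3 cells: correlation undefined")
  if (n < 10) warning("fewer than 10 cells; correlations are unstable")
  if (length(scores) != n) stop("scores must align to the matrix columns")
  xc <- x - rowMeans(x)
  sc <- scores - mean(scores)
  den2 <- rowSums(xc^2) * sum(sc^2)
  zeroVar <- rowSums(xc^2) == 0 | sum(sc^2) == 0
  r <- as.vector(xc %*% sc) / sqrt(pmax(den2, .Machine$double.eps))
  r[zeroVar] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  pAdj <- if (adjust) stats::p.adjust(p, "BH") else p
  selected <- !zeroVar & !is.na(pAdj) & pAdj < alpha & r > rMin
  data.frame(gene = rownames(x), r = r, p = p, selected = selected,
             zero_var = zeroVar, row.names = NULL)
}
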