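# Independent brute-force oracles. These deliberately use explicit loops and
# textbook formulas, sharing no code path with the package implementation.

# Descending per-cell ranks with zero unification: explicit per-column loop,
# midranks assigned by scanning sorted positions.
naiveRankColumn <- function(v, m) {
  r <- rep(m, length(v))
  nz <- which(v > 0)
  if (length(nz)) {
    vals <- v[nz]
    ord <- nz[order(-vals)]
    i <- 1
    pos <- 1
    while (i <= length(ord)) {
      j <- i
      while (j < length(ord) && v[ord[j + 1]] == v[ord[i]]) j <- j + 1
      mid <- mean(pos:(pos + (j - i)))
      for (t in i:j) r[ord[t]] <- mid
      pos <- pos + (j - i + 1)
      i <- j + 1
    }
  }
  r
}

naiveRankMatrix <- function(expr) {
  m <- nrow(expr)
  out <- matrix(NA_real_, m, ncol(expr), dimnames = dimnames(expr))
  for (j in seq_len(ncol(expr))) out[, j] <- naiveRankColumn(expr[, j], m)
  out
}

# Textbook rank-space FC / pooled t with explicit loops.
naiveRankDe <- function(ranks, isMet) {
  nx <- sum(isMet); ny <- sum(!isMet); n <- nx + ny
  out <- data.frame(FC = numeric(nrow(ranks)), t = numeric(nrow(ranks)),
                    p = numeric(nrow(ranks)))
  for (i in seq_len(nrow(ranks))) {
    xi <- ranks[i, isMet]; yi <- ranks[i, !isMet]
    mx <- sum(xi) / nx; my <- sum(yi) / ny
    all <- c(xi, yi)
    mu <- sum(all) / n
    si <- sqrt(sum((all - mu)^2) / (n - 1))
    tt <- (mx - my) / (si * sqrt(1 / nx + 1 / ny))
    out$FC[i] <- mx / my
    out$t[i] <- tt
    out$p[i] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  out
}

# Full running-sum walk for the weighted KS enrichment score.
naiveEnrichmentScore <- function(inSet, w) {
  G <- length(inSet)
  S <- sum(inSet)
  tot <- sum(w[inSet])
  run <- 0; best <- 0
  for (i in seq_len(G)) {
    run <- run + if (inSet[i]) w[i] / tot else -1 / (G - S)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Explicit recovery-curve summation for the AUCell-style score.
naiveAucell <- function(expr, geneSet, topFraction = 0.05) {
  G <- length(expr)
  ord <- names(expr)[order(-expr, names(expr))]
  W <- ceiling(topFraction * G)
  present <- sum(geneSet %in% names(expr))
  if (present == 0) return(0)
  area <- 0
  hits <- 0
  for (t in seq_len(W)) {
    if (ord[t] %in% geneSet) hits <- hits + 1
    area <- area + hits
  }
  maxArea <- 0; h <- 0
  for (t in seq_len(W)) {
    if (h < min(present, W)) h <- h + 1
    maxArea <- maxArea + h
  }
  area / maxArea
}

# Explicit walk for the single-sample rank-weighted score (raw statistic).
naiveSsRaw <- function(v, inSet, alpha) {
  G <- length(v)
  rk <- rank(-v, ties.method = "average")
  ord <- order(rk)
  S <- sum(inSet)
  wTot <- 0
  for (i in seq_len(G)) if (inSet[i]) wTot <- wTot + rk[i]^(-alpha)
  run <- 0; acc <- 0
  for (t in seq_len(G)) {
    i <- ord[t]
    run <- run + if (inSet[i]) rk[i]^(-alpha) / wTot else -1 / (G - S)
    acc <- acc + run
  }
  unname(acc)
}

# Exact hypergeometric upper tail by pmf summation with choose().
naiveHyperTail <- function(k, K, n, N) {
  tot <- 0
  for (x in k:min(K, n))
    tot <- tot + choose(K, x) * choose(N - K, n - x) / choose(N, n)
  min(1, tot)
}

# QC filter as a naive double loop over genes then cells.
naiveQcFilter <- function(counts, minCellsPerGene, minGenesPerCell) {
  keepG <- logical(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    nc <- 0
    for (j in seq_len(ncol(counts))) if (counts[i, j] > 0) nc <- nc + 1
    keepG[i] <- nc >= minCellsPerGene
  }
  sub <- counts[keepG, , drop = FALSE]
  keepC <- logical(ncol(sub))
  for (j in seq_len(ncol(sub))) {
    ng <- 0
    for (i in seq_len(nrow(sub))) if (sub[i, j] > 0) ng <- ng + 1
    keepC[j] <- ng >= minGenesPerCell
  }
  sub[, keepC, drop = FALSE]
}

# Exhaustive label-permutation oracle for the interaction score, explicit
# loops over every permutation of the cells.
naiveExactInteractionP <- function(x, labels, ligand, receptor, sender,
                                   receiver) {
  n <- length(labels)
  permute <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in permute(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  scoreFor <- function(lab) {
    ls <- 0; nl <- 0; rs <- 0; nr <- 0
    for (j in seq_len(n)) {
      if (lab[j] == sender) { ls <- ls + x[ligand, j]; nl <- nl + 1 }
      if (lab[j] == receiver) { rs <- rs + x[receptor, j]; nr <- nr + 1 }
    }
    (ls / nl + rs / nr) / 2
  }
  obs <- scoreFor(labels)
  perms <- permute(seq_len(n))
  cnt <- 0
  for (p in perms) if (scoreFor(labels[p]) >= obs - 1e-12) cnt <- cnt + 1
  cnt / length(perms)
}

# Minimal two-type configuration for fast structural tests.
tinyConfig <- function(seed = 1, cellsPerDataset = 60, nGenes = 120, ...) {
  simConfig(cellsPerDataset = cellsPerDataset, nGenes = nGenes, seed = seed,
            cellTypes = list(
              list(name = "A", proportion = 0.5,
                   markers = sprintf("g%04d", 1:8), boost = log(8)),
              list(name = "B", proportion = 0.5,
                   markers = sprintf("g%04d", 9:16), boost = log(8))), ...)
}

# Small helper: simulated cohort with normalized datasets and truth labels.
preparedCohort <- function(cfg) {
  co <- simulateCohort(cfg)
  truth <- co$truth$cells
  co$norm <- lapply(co$datasets, normalizeLog)
  co$labels <- lapply(co$norm, function(cm)
    truth$cell_type[match(colnames(cm), truth$barcode)])
  co
}
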