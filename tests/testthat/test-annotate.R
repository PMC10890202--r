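clusteredTiny <- function(seed = 4, cells = 300) {
  co <- preparedCohort(tinyConfig(seed = seed, cellsPerDataset = cells))
  cm <- co$norm[[1]]
  cm <- embedCluster(cm, selectHvg(cm, 60), nPcs = 10, seed = 9)
  list(cm = cm, co = co)
}

test_that("planted markers surface in their own cluster's marker list", {
  ct <- clusteredTiny()
  mks <- findClusterMarkers(ct$cm)
  truthLab <- ct$co$labels[[1]]
  for (key in names(mks)) {
    cells <- truthLab[ct$cm$cluster == mks[[key]]$cluster]
    own <- names(which.max(table(cells)))
    planted <- if (own == "A") sprintf("g%04d", 1:8) else sprintf("g%04d", 9:16)
    expect_gte(length(intersect(mks[[key]]$markers, planted)), 7)
  }
})

test_that("randomly split identical cells yield essentially no markers", {
  cfg <- simConfig(nDatasetsPerCondition = 1, cellsPerDataset = 600,
                   nGenes = 120, seed = 31,
                   cellTypes = list(list(name = "only", proportion = 1,
                                         markers = character(), boost = 0)))
  co <- preparedCohort(cfg)
  cm <- co$norm[[1]]
  set.seed(1)
  cm$cluster <- sample(c(0L, 1L), ncol(cm), replace = TRUE)
  mks <- findClusterMarkers(cm)
  expect_lte(stats::median(vapply(mks, function(m) length(m$markers), 1L)), 1)
})

test_that("single-cell clusters get empty markers with a warning", {
  ct <- clusteredTiny(seed = 6, cells = 100)
  cm <- ct$cm
  cm$cluster[1] <- 99L
  expect_warning(mks <- findClusterMarkers(cm), "fewer than 2 cells")
  expect_length(mks[["99"]]$markers, 0)
})

test_that("running-sum enrichment score equals the brute-force walk", {
  set.seed(12)
  for (trial in 1:200) {
    G <- 50
    w <- abs(rnorm(G))
    S <- sample(2:10, 1)
    pos <- sort(sample.int(G, S))
    inSet <- seq_len(G) %in% pos
    expect_equal(scRankCompare:::.enrichmentScore(pos, w, G),
                 naiveEnrichmentScore(inSet, w), tolerance = 1e-12)
  }
})

test_that("the enrichment score agrees with an independent library implementation", {
  skip_if_not_installed("fgsea")
  set.seed(18)
  for (trial in 1:25) {
    G <- sample(30:80, 1)
    w <- sort(abs(rnorm(G)), decreasing = TRUE)
    pos <- sort(sample.int(G, sample(3:12, 1)))
    expect_equal(scRankCompare:::.enrichmentScore(pos, w, G),
                 fgsea::calcGseaStat(w, selectedStats = pos, gseaParam = 1),
                 tolerance = 1e-10)
  }
})

test_that("a signature matching the top-ranked genes wins the NES contest", {
  mk <- list(cluster = 0L,
             table = data.frame(gene = sprintf("g%02d", 1:20),
                                logFC = seq(2, -1.8, length.out = 20),
                                p = 0.01, padj = 0.01),
             markers = sprintf("g%02d", 1:6))
  db <- SignatureDB(list(top = sprintf("g%02d", 1:5),
                         other = sprintf("g%02d", 15:19)))
  res <- gseaAnnotate(mk, db, nPerm = 200, seed = 1)
  expect_equal(res$call, "top")
  expect_gt(res$table$ES[res$table$type == "top"], 0)
  db2 <- SignatureDB(list(top = sprintf("g%02d", 1:5), absent = c("zz1", "zz2")))
  expect_warning(res2 <- gseaAnnotate(mk, db2, nPerm = 50, seed = 1), "skipped")
  expect_identical(res2$table$type, "top")
})

test_that("marker-overlap p equals the exact hypergeometric tail", {
  mk <- list(cluster = 0L, table = NULL, markers = sprintf("g%02d", 1:5))
  universe <- sprintf("g%02d", 1:20)
  db <- SignatureDB(list(match = sprintf("g%02d", 1:5),
                         other = sprintf("g%02d", 10:14)))
  res <- overlapAnnotate(mk, db, universe)
  expect_equal(res$call, "match")
  expect_equal(res$table$p[res$table$type == "match"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_false(res$lowConfidence)

  dbMiss <- SignatureDB(list(far = sprintf("g%02d", 15:18)))
  res2 <- overlapAnnotate(mk, dbMiss, universe)
  expect_true(res2$lowConfidence)
  expect_equal(res2$table$p, 1)
})

test_that("overlap annotation agrees with the pmf-summation oracle on random draws", {
  set.seed(5)
  for (trial in 1:50) {
    N <- sample(20:40, 1)
    universe <- sprintf("u%02d", seq_len(N))
    mk <- list(markers = sample(universe, sample(3:8, 1)))
    sig <- sample(universe, sample(3:10, 1))
    res <- overlapAnnotate(mk, SignatureDB(list(s = sig)), universe)
    k <- length(intersect(mk$markers, sig))
    expect_equal(res$table$p,
                 naiveHyperTail(k, length(sig), length(mk$markers), N),
                 tolerance = 1e-12)
  }
})

test_that("AUCell score hits its extremes and matches the step-curve oracle", {
  expr <- stats::setNames(seq(100, 1, by = -1), sprintf("g%03d", 1:100))
  expect_equal(aucellScore(expr, sprintf("g%03d", 1:5), 0.05), 1)
  expect_equal(aucellScore(expr, sprintf("g%03d", 90:94), 0.05), 0)
  set.seed(9)
  for (trial in 1:100) {
    e <- stats::setNames(sample(100), sprintf("g%03d", 1:100))
    set <- sample(names(e), sample(3:10, 1))
    expect_equal(aucellScore(e, set, 0.1), naiveAucell(e, set, 0.1),
                 tolerance = 1e-12)
  }
  expect_warning(a0 <- aucellScore(expr, c("none1", "none2")), "absent")
  expect_equal(a0, 0)
})

test_that("AUCell score is invariant to monotone expression transforms", {
  set.seed(2)
  e <- stats::setNames(rexp(200), sprintf("g%03d", 1:200))
  set <- sample(names(e), 12)
  a <- aucellScore(e, set)
  expect_identical(aucellScore(log1p(e) * 3 + 1, set), a)
  expect_identical(aucellScore(e^2, set), a)
})

test_that("ensemble annotation labels planted types and records the path", {
  ct <- clusteredTiny(seed = 13, cells = 300)
  ann <- ensembleAnnotate(ct$cm, ct$co$markerDB, nPerm = 200, seed = 2)
  lab <- annotateCells(ct$cm, ann)
  acc <- mean(lab == ct$co$labels[[1]])
  expect_gte(acc, 0.95)
  agree <- ann$decision_path == "agreement"
  expect_true(all(is.na(ann$aucell_gsea[agree])))
})

test_that("conflicting annotators are resolved by the higher AUCell activity", {
  # construct a cluster whose markers overlap signature B slightly better,
  # while the cells actually express signature A highly
  set.seed(7)
  G <- 200
  genes <- sprintf("g%03d", seq_len(G))
  sigA <- genes[1:10]; sigB <- genes[c(11:16, 101:104)]
  m <- matrix(rpois(G * 80, 1), G, 80, dimnames = list(genes, sprintf("c%02d", 1:80)))
  m[1:16, 41:80] <- m[1:16, 41:80] + matrix(rpois(16 * 40, 20), 16)  # A high
  cm <- normalizeLog(CountMatrix(m, "d", "primary"))
  cm$cluster <- rep(c(0L, 1L), each = 40)
  mks <- findClusterMarkers(cm)
  db <- SignatureDB(list(A = sigA, B = sigB))
  ann <- ensembleAnnotate(cm, db, nPerm = 300, seed = 3)
  row <- ann[ann$cluster == 1L, ]
  if (row$decision_path == "aucell_tiebreak") {
    expect_equal(row$final_call, "A")
    expect_gt(row$aucell_gsea + row$aucell_overlap, 0)
  } else {
    expect_equal(row$final_call, "A")  # annotators already agreed on truth
  }
  # direct check of the tie-break rule on a forced conflict
  x <- as.matrix(SummarizedExperiment::assay(cm, "lognorm"))
  aA <- mean(apply(x[, 41:80], 2, aucellScore, geneSet = sigA))
  aB <- mean(apply(x[, 41:80], 2, aucellScore, geneSet = sigB))
  expect_gt(aA, aB)
})
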