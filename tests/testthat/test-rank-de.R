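blockOf <- function(expr, genes, condition) {
  list(expr = expr, genes = genes, condition = condition)
}

mkExpr <- function(v, genes, cell = "c1") {
  matrix(v, length(v), 1, dimnames = list(genes, cell))
}

test_that("per-cell descending ranks follow the zero-unification rule", {
  genes <- c("gA", "gB", "gC", "gD")
  rmx <- buildRankMatrix(list(
    blockOf(mkExpr(c(5, 3, 0, 1), genes), genes, "metastatic"),
    blockOf(mkExpr(c(1, 2, 3, 4), genes, "c2"), genes, "primary")))
  expect_equal(unname(rankValues(rmx)[, "c1"]), c(1, 2, 4, 3))

  rm0 <- buildRankMatrix(list(
    blockOf(mkExpr(c(0, 0, 0, 0), genes), genes, "metastatic"),
    blockOf(mkExpr(c(1, 2, 3, 4), genes, "c2"), genes, "primary")))
  expect_equal(unname(rankValues(rm0)[, "c1"]), c(4, 4, 4, 4))
})

test_that("the gene union merges top lists and absent genes rank m", {
  gsA <- c("A", "B", "C"); gsB <- c("B", "C", "D")
  e1 <- mkExpr(c(3, 2, 1), gsA)
  e2 <- mkExpr(c(1, 2, 3), gsB, "c2")
  rmx <- buildRankMatrix(list(blockOf(e1, gsA, "metastatic"),
                              blockOf(e2, gsB, "primary")))
  expect_equal(nGenes(rmx), 4L)
  expect_identical(rmx@genes, c("A", "B", "C", "D"))
  expect_equal(rankValues(rmx)["D", "c1"], 4)
  expect_equal(rankValues(rmx)["A", "c2"], 4)
  expect_error(buildRankMatrix(list(blockOf(e1, gsA, "metastatic"))),
               "one-sided comparison")
})

test_that("genes outside a dataset's top list are zeroed before ranking", {
  genes <- c("A", "B", "C")
  e <- mkExpr(c(1, 5, 3), genes)
  rmx <- buildRankMatrix(list(
    blockOf(e, c("A", "B"), "metastatic"),            # C not in top list
    blockOf(mkExpr(c(1, 1, 1), genes, "c2"), c("A", "B", "C"), "primary")))
  expect_equal(rankValues(rmx)["C", "c1"], 3)          # treated as 0
  expect_equal(unname(rankValues(rmx)[, "c1"]), c(2, 1, 3))
})

test_that("rank matrix equals the naive reference on random sparse inputs", {
  set.seed(77)
  for (trial in 1:40) {
    m <- sample(20:120, 1); n <- sample(4:30, 1)
    expr <- matrix(rpois(m * n, 0.8), m, n,
                   dimnames = list(sprintf("g%03d", 1:m), sprintf("c%03d", 1:n)))
    expr[sample(length(expr), length(expr) %/% 4)] <- 0
    half <- n %/% 2
    rmx <- buildRankMatrix(list(
      blockOf(expr[, seq_len(half), drop = FALSE], rownames(expr), "metastatic"),
      blockOf(expr[, (half + 1):n, drop = FALSE], rownames(expr), "primary")))
    expect_identical(unname(rankValues(rmx)), unname(naiveRankMatrix(expr)))
  }
})

mkRank <- function(ranks, nx) {
  m <- nrow(ranks)
  cond <- factor(rep(c("metastatic", "primary"), c(nx, ncol(ranks) - nx)),
                 levels = c("metastatic", "primary"))
  new("RankMatrix", genes = rownames(ranks), ranks = ranks, condition = cond,
      nx = as.integer(nx), ny = as.integer(ncol(ranks) - nx))
}

test_that("fold change and t carry the documented direction convention", {
  ranks <- rbind(gU = rep(c(1, 3), each = 5), gN = rep(2, 10),
                 gX = rep(c(3, 1), each = 5))
  colnames(ranks) <- sprintf("c%d", 1:10)
  res <- rankDeTest(mkRank(ranks, 5), alpha = 0.05)
  up <- res[res$gene == "gU", ]
  expect_equal(up$meanXi, 1); expect_equal(up$meanYi, 3)
  expect_equal(up$FC, 1 / 3)
  expect_lt(up$t, 0)
  expect_equal(up$direction, "up_in_metastatic")
  null <- res[res$gene == "gN", ]
  expect_equal(null$FC, 1)
  expect_true(null$zero_sd)
  expect_equal(null$direction, "ns")
})

test_that("identical rank distributions give t = 0, FC = 1, ns", {
  ranks <- rbind(g1 = c(1, 2, 1, 2), g2 = c(2, 1, 2, 1))
  colnames(ranks) <- sprintf("c%d", 1:4)
  res <- rankDeTest(mkRank(ranks, 2))
  expect_equal(res$t, c(0, 0))
  expect_equal(res$FC, c(1, 1))
  expect_identical(res$direction, c("ns", "ns"))
})

test_that("FC, t and p match explicit-loop recomputation on random rank matrices", {
  set.seed(31)
  for (trial in 1:20) {
    m <- sample(50:200, 1); n <- sample(10:60, 1)
    nx <- sample(4:(n - 4), 1)
    expr <- matrix(rexp(m * n) * rbinom(m * n, 1, 0.7), m, n,
                   dimnames = list(sprintf("g%03d", 1:m), sprintf("c%03d", 1:n)))
    ranks <- naiveRankMatrix(expr)
    res <- rankDeTest(mkRank(ranks, nx))
    ref <- naiveRankDe(ranks, rep(c(TRUE, FALSE), c(nx, n - nx)))
    ok <- !res$zero_sd
    expect_equal(res$FC[ok], ref$FC[ok], tolerance = 1e-10)
    expect_equal(res$t[ok], ref$t[ok], tolerance = 1e-10)
    expect_equal(res$p[ok], ref$p[ok], tolerance = 1e-10)
  }
})

test_that("swapping condition labels maps FC to 1/FC and t to -t exactly", {
  set.seed(13)
  expr <- matrix(rpois(80 * 20, 1.5), 80, 20,
                 dimnames = list(sprintf("g%02d", 1:80), sprintf("c%02d", 1:20)))
  ranks <- naiveRankMatrix(expr)
  a <- rankDeTest(mkRank(ranks, 8))
  swapped <- mkRank(cbind(ranks[, 9:20], ranks[, 1:8]), 12)
  b <- rankDeTest(swapped)
  ok <- !a$zero_sd
  expect_equal(b$FC[ok], 1 / a$FC[ok], tolerance = 1e-14)
  expect_identical(b$t[ok], -a$t[ok])
})

test_that("a per-dataset positive scalar leaves the rank matrix bit-identical", {
  set.seed(21)
  for (trial in 1:5) {
    expr1 <- matrix(rpois(60 * 10, 1), 60, 10,
                    dimnames = list(sprintf("g%02d", 1:60), sprintf("a%02d", 1:10)))
    expr2 <- matrix(rpois(60 * 12, 1), 60, 12,
                    dimnames = list(sprintf("g%02d", 1:60), sprintf("b%02d", 1:12)))
    g <- rownames(expr1)
    base <- buildRankMatrix(list(blockOf(expr1, g, "metastatic"),
                                 blockOf(expr2, g, "primary")))
    scaled <- buildRankMatrix(list(blockOf(expr1 * runif(1, 0.1, 9), g, "metastatic"),
                                   blockOf(expr2, g, "primary")))
    expect_identical(rankValues(base), rankValues(scaled))
  }
})

test_that("ranks are invariant to strictly increasing per-cell transforms", {
  set.seed(3)
  expr <- matrix(rpois(50 * 8, 2), 50, 8,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:8)))
  g <- rownames(expr)
  base <- buildRankMatrix(list(blockOf(expr[, 1:4], g, "metastatic"),
                               blockOf(expr[, 5:8], g, "primary")))
  mono <- log1p(expr) * 7
  trans <- buildRankMatrix(list(blockOf(mono[, 1:4], g, "metastatic"),
                                blockOf(mono[, 5:8], g, "primary")))
  expect_identical(rankValues(base), rankValues(trans))
})

test_that("too few cells per condition is an error", {
  ranks <- rbind(g1 = c(1, 2, 1), g2 = c(2, 1, 2))
  colnames(ranks) <- sprintf("c%d", 1:3)
  expect_error(rankDeTest(mkRank(ranks, 1)), "insufficient cells")
})

test_that("the literal no-square-root denominator is available behind a flag", {
  ranks <- naiveRankMatrix(matrix(rpois(40 * 12, 1.2), 40, 12,
                                  dimnames = list(sprintf("g%02d", 1:40),
                                                  sprintf("c%02d", 1:12))))
  std <- rankDeTest(mkRank(ranks, 6))
  raw <- rankDeTest(mkRank(ranks, 6), rawDenominator = TRUE)
  ok <- !std$zero_sd
  expect_equal(raw$t[ok], std$t[ok] / sqrt(1 / 6 + 1 / 6), tolerance = 1e-12)
})

test_that("top genes per dataset are mean-sorted with name-order ties", {
  co <- preparedCohort(tinyConfig(seed = 14, cellsPerDataset = 80))
  cm <- co$norm[[1]]
  lab <- co$labels[[1]]
  top <- topGenesPerDataset(cm, lab, "A", k = 5000)
  expect_equal(length(top), nrow(cm))
  x <- as.matrix(SummarizedExperiment::assay(cm, "lognorm"))[, lab == "A"]
  mu <- rowMeans(x)
  ref <- names(mu)[order(-mu, names(mu))]
  expect_identical(top, ref)
  expect_identical(topGenesPerDataset(cm, lab, "A", k = 3), ref[1:3])
  expect_warning(none <- topGenesPerDataset(cm, lab, "missing"), "no cells")
  expect_length(none, 0)
})
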