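toyMatrix <- function(G, n, seed = 1, lambda = 2) {
  set.seed(seed)
  matrix(rpois(G * n, lambda), G, n,
         dimnames = list(sprintf("g%02d", 1:G), sprintf("c%02d", 1:n)))
}

test_that("input contracts: empty pairs, unknown genes, tiny types", {
  x <- toyMatrix(10, 20)
  lab <- rep(c("A", "B"), each = 10)
  expect_error(interactionTest(x, lab, data.frame(ligand = character(),
                                                  receptor = character())),
               "empty pair table")
  expect_warning(
    res <- interactionTest(x, lab,
                           data.frame(ligand = c("g01", "zz"),
                                      receptor = c("g02", "g03")),
                           nPerm = 20, seed = 1),
    "skipped")
  expect_setequal(unique(res$ligand), "g01")
  expect_error(interactionTest(x, rep("A", 20),
                               data.frame(ligand = "g01", receptor = "g02")),
               "2 cell types")
  expect_error(interactionTest(x, c(rep("A", 17), rep("B", 3)),
                               data.frame(ligand = "g01", receptor = "g02")),
               ">= 5 cells")
})

test_that("lowly detected ligands or receptors are excluded, not tested", {
  x <- toyMatrix(6, 30, lambda = 3)
  x["g01", ] <- 0; x["g01", 1] <- 1   # ligand detected in 1/15 sender cells
  lab <- rep(c("A", "B"), each = 15)
  res <- interactionTest(x, lab, data.frame(ligand = "g01", receptor = "g02"),
                         nPerm = 50, seed = 2, minFrac = 0.5)
  row <- res[res$sender == "A" & res$receiver == "B", ]
  expect_true(row$excluded)
  expect_true(is.na(row$p))
  expect_false(row$significant)
})

test_that("identically expressed genes are not called significant", {
  set.seed(4)
  x <- toyMatrix(8, 1200, seed = 4, lambda = 5)
  lab <- sample(rep(c("A", "B", "C"), 400))
  res <- interactionTest(x, lab, data.frame(ligand = "g01", receptor = "g02"),
                         nPerm = 400, seed = 9)
  expect_true(all(res$p > 0 & res$p <= 1))
  # under exchangeability the large-sample p should rarely be extreme
  expect_gt(min(res$p), 0.005)
})

test_that("permutation p matches exhaustive enumeration on small toys", {
  set.seed(6)
  for (trial in 1:3) {
    n <- 6
    x <- matrix(rpois(4 * n, 3) + 1, 4, n,
                dimnames = list(c("L", "R", "o1", "o2"), sprintf("c%d", 1:n)))
    lab <- c("A", "A", "B", "B", "C", "C")
    res <- interactionTest(x, lab, data.frame(ligand = "L", receptor = "R"),
                           seed = 1, exact = TRUE, minFrac = 0)
    for (i in seq_len(nrow(res))) {
      ref <- naiveExactInteractionP(x, lab, "L", "R",
                                    res$sender[i], res$receiver[i])
      expect_equal(res$p[i], ref, tolerance = 1e-12)
    }
  }
})

test_that("planted sender/receiver interactions reach the smallest possible p", {
  co <- preparedCohort(tinyConfig(
    seed = 19, cellsPerDataset = 400,
    lrSpec = data.frame(ligand = "g0040", receptor = "g0041",
                        sender = "A", receiver = "B")))
  x <- as.matrix(SummarizedExperiment::assay(co$norm[[1]], "lognorm"))
  lab <- co$labels[[1]]
  nPerm <- 300
  res <- interactionTest(x, lab, data.frame(ligand = "g0040", receptor = "g0041"),
                         nPerm = nPerm, seed = 3)
  row <- res[res$sender == "A" & res$receiver == "B", ]
  expect_equal(row$p, 1 / (nPerm + 1))
  expect_true(row$significant)
})

test_that("permutation p-values are reproducible for a fixed seed", {
  x <- toyMatrix(6, 60, seed = 8)
  lab <- rep(c("A", "B", "C"), 20)
  pairs <- data.frame(ligand = c("g01", "g03"), receptor = c("g02", "g04"))
  a <- interactionTest(x, lab, pairs, nPerm = 100, seed = 42)
  b <- interactionTest(x, lab, pairs, nPerm = 100, seed = 42)
  expect_identical(a, b)
})

test_that("interaction shares count both endpoints and align cohorts", {
  one <- data.frame(ligand = "L", receptor = "R", sender = "A",
                    receiver = "B", score = 1, p = 0.001,
                    significant = TRUE, excluded = FALSE)
  sh <- interactionShare(list(met = one))
  expect_equal(sh$share_met[sh$type == "A"], 1)
  expect_equal(sh$share_met[sh$type == "B"], 1)

  none <- one; none$significant <- FALSE
  expect_warning(sh0 <- interactionShare(list(met = none)), "no significant")
  expect_equal(nrow(sh0), 0L)

  two <- rbind(one, data.frame(ligand = "L2", receptor = "R2", sender = "A",
                               receiver = "C", score = 1, p = 0.001,
                               significant = TRUE, excluded = FALSE))
  expect_warning(sh2 <- interactionShare(list(met = two, pri = none)),
                 "shares are 0")
  expect_equal(sh2$share_met[sh2$type == "A"], 1)
  expect_equal(sh2$share_met[sh2$type == "B"], 0.5)
  expect_equal(sh2$share_pri, rep(0, 3))
})

test_that("types carrying the planted interactions take the top share", {
  co <- preparedCohort(tinyConfig(
    seed = 23, cellsPerDataset = 300,
    lrSpec = data.frame(ligand = c("g0040", "g0042"),
                        receptor = c("g0041", "g0043"),
                        sender = c("A", "A"), receiver = c("B", "A"))))
  x <- as.matrix(SummarizedExperiment::assay(co$norm[[1]], "lognorm"))
  res <- interactionTest(x, co$labels[[1]],
                         data.frame(ligand = c("g0040", "g0042"),
                                    receptor = c("g0041", "g0043")),
                         nPerm = 200, seed = 5)
  sh <- interactionShare(list(met = res))
  expect_equal(sh$type[which.max(sh$share_met)], "A")
})
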