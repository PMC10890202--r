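#' Permutation test for ligand-receptor communication
#'
#' For every ligand-receptor pair and every ordered (sender, receiver)
#' cell-type combination, the observed interaction score is the mean of the
#' ligand's mean normalized expression in the sender type and the
#' receptor's mean in the receiver type. The null distribution shuffles the
#' type labels over all cells \code{nPerm} times and recomputes the score;
#' the one-sided p-value is \code{(#\{null >= observed\} + 1) / (nPerm + 1)}.
#' Combinations where the ligand is detected in fewer than \code{minFrac}
#' of sender cells (or the receptor in fewer than \code{minFrac} of
#' receiver cells) are excluded rather than tested.
#'
#' With \code{exact = TRUE} the full set of label permutations is
#' enumerated (all \code{n!} column orders; feasible for small toys) and
#' the p-value is the exact fraction \code{#\{null >= observed\} / n!},
#' which includes the observed labeling itself.
#'
#' @param x normalized genes-by-cells matrix.
#' @param labels cell-type label per column of \code{x}.
#' @param pairs data.frame with columns \code{ligand}, \code{receptor}.
#' @param nPerm number of label permutations (default 1000).
#' @param seed RNG seed.
#' @param minFrac minimum detection fraction (default 0.1).
#' @param alpha significance level on the raw permutation p (default 0.05).
#' @param exact enumerate all label permutations instead of sampling.
#' @return data.frame with one row per tested or excluded combination:
#'   \code{ligand}, \code{receptor}, \code{sender}, \code{receiver},
#'   \code{score}, \code{p}, \code{significant}, \code{excluded}.
#' @export
interactionTest <- function(x, labels, pairs, nPerm = 1000, seed = 1,
                            minFrac = 0.1, alpha = 0.05, exact = FALSE) {
  if (!nrow(pairs)) stop("empty pair table")
  types <- sort(unique(labels))
  if (length(types) < 2) stop("at least 2 cell types are required")
  sizes <- table(labels)
  if (!exact && any(sizes < 5)) stop("every cell type needs >= 5 cells")
  known <- pairs$ligand %in% rownames(x) & pairs$receptor %in% rownames(x)
  if (any(!known)) {
    warning(sum(!known), " pair(s) with genes absent from the matrix skipped")
    pairs <- pairs[known, , drop = FALSE]
    if (!nrow(pairs)) stop("empty pair table")
  }
  genes <- unique(c(pairs$ligand, pairs$receptor))
  sub <- t(as.matrix(x[genes, , drop = FALSE]))  # cells x genes
  lab <- factor(labels, levels = types)
  nPerType <- as.vector(table(lab))
  typeMeans <- function(l) rowsum(sub, l, reorder = TRUE) / nPerType

  obsM <- typeMeans(lab)
  detFrac <- rowsum((sub > 0) + 0, lab, reorder = TRUE) / nPerType

  combos <- expand.grid(pi = seq_len(nrow(pairs)), sender = types,
                        receiver = types, stringsAsFactors = FALSE)
  res <- data.frame(ligand = pairs$ligand[combos$pi],
                    receptor = pairs$receptor[combos$pi],
                    sender = combos$sender, receiver = combos$receiver)
  res$score <- (obsM[cbind(res$sender, res$ligand)] +
                obsM[cbind(res$receiver, res$receptor)]) / 2
  res$excluded <- detFrac[cbind(res$sender, res$ligand)] < minFrac |
    detFrac[cbind(res$receiver, res$receptor)] < minFrac

  n <- length(lab)
  exceed <- numeric(nrow(res))
  if (exact) {
    perms <- .allPermutations(n)
    for (i in seq_len(nrow(perms))) {
      pm <- typeMeans(lab[perms[i, ]])
      nullScore <- (pm[cbind(res$sender, res$ligand)] +
                    pm[cbind(res$receiver, res$receptor)]) / 2
      exceed <- exceed + (nullScore >= res$score)
    }
    res$p <- exceed / nrow(perms)
  } else {
    set.seed(seed)
    for (i in seq_len(nPerm)) {
      pm <- typeMeans(lab[sample.int(n)])
      nullScore <- (pm[cbind(res$sender, res$ligand)] +
                    pm[cbind(res$receiver, res$receptor)]) / 2
      exceed <- exceed + (nullScore >= res$score)
    }
    res$p <- (exceed + 1) / (nPerm + 1)
  }
  res$p[res$excluded] <- NA_real_
  res$score[res$excluded] <- NA_real_
  res$significant <- !res$excluded & !is.na(res$p) & res$p < alpha
  res
}

# All n! permutations of seq_len(n) as rows (small n only).
.allPermutations <- function(n) {
  if (n > 9) stop("exact enumeration supported only for n <= 9 cells")
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], rec(v[-i]))))
  }
  rec(seq_len(n))
}

#' Per-type share of significant interactions
#'
#' For each cohort, counts the significant interactions each cell type
#' participates in (as sender or receiver; a self-interaction counts once)
#' and divides by the cohort's total number of significant interactions.
#' Shares over types can therefore sum to at most 2. Cohort columns are
#' aligned on the union of type names, with 0 for absent types.
#'
#' @param results named list (one element per cohort) of
#'   [interactionTest()] result data.frames.
#' @return data.frame with a \code{type} column and one share column per
#'   cohort.
#' @export
interactionShare <- function(results) {
  sig <- lapply(results, function(r) r[r$significant, , drop = FALSE])
  types <- sort(unique(unlist(lapply(sig, function(r)
    c(r$sender, r$receiver)))))
  if (!length(types)) {
    warning("no significant interactions in any cohort")
    return(data.frame(type = character()))
  }
  out <- data.frame(type = types)
  for (nm in names(results)) {
    r <- sig[[nm]]
    tot <- nrow(r)
    if (tot == 0) {
      warning("cohort '", nm, "' has no significant interactions; shares are 0")
      out[[paste0("share_", nm)]] <- 0
    } else {
      cnt <- vapply(types, function(ty)
        sum(r$sender == ty | r$receiver == ty), numeric(1))
      out[[paste0("share_", nm)]] <- cnt / tot
    }
  }
  out
}
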