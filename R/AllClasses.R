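#' @import methods
#' @importFrom Matrix Matrix rowSums colSums t readMM writeMM
#' @importClassesFrom Matrix dgCMatrix
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment reducedDim reducedDim<-
#' @importFrom SummarizedExperiment assay assay<- assayNames colData colData<- rowData
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

VALID_CONDITIONS <- c("primary", "metastatic")

#' Per-dataset count matrix with cohort metadata
#'
#' A \code{CountMatrix} is a \linkS4class{SingleCellExperiment} carrying one
#' dataset's gene-by-cell raw counts in the \code{"counts"} assay, together
#' with the dataset identifier and the cohort condition
#' (\code{"primary"} or \code{"metastatic"}). Downstream stages add the
#' \code{"lognorm"} assay, a \code{"PCA"} reduced dimension, and a
#' \code{cluster} column in \code{colData}.
#'
#' Validity requires non-negative integer counts, unique gene symbols and
#' unique cell barcodes, and a condition in \code{c("primary", "metastatic")}.
#'
#' @slot datasetId single string identifying the dataset.
#' @slot condition cohort label, \code{"primary"} or \code{"metastatic"}.
#' @export
setClass("CountMatrix",
  contains = "SingleCellExperiment",
  slots = c(datasetId = "character", condition = "character")
)

setValidity("CountMatrix", function(object) {
  msg <- character()
  if (length(object@datasetId) != 1L || !nzchar(object@datasetId))
    msg <- c(msg, "datasetId must be a single non-empty string")
  if (length(object@condition) != 1L || !object@condition %in% VALID_CONDITIONS)
    msg <- c(msg, "condition must be 'primary' or 'metastatic'")
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else {
    cts <- assay(object, "counts")
    x <- if (is(cts, "sparseMatrix")) cts@x else as.vector(cts)
    if (length(x) && (any(x < 0) || any(x != round(x))))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene symbols must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "cell barcodes must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct a CountMatrix
#'
#' @param counts gene-by-cell matrix of non-negative integer counts (dense or
#'   sparse); rownames are gene symbols, colnames are cell barcodes.
#' @param datasetId dataset identifier.
#' @param condition cohort condition, \code{"primary"} or \code{"metastatic"}.
#' @param genes,cells optional identifier vectors used when \code{counts}
#'   lacks dimnames.
#' @return a validated \linkS4class{CountMatrix}.
#' @examples
#' m <- matrix(c(1L, 0L, 2L, 3L, 0L, 0L), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:2)))
#' cm <- CountMatrix(m, datasetId = "d1", condition = "primary")
#' @export
CountMatrix <- function(counts, datasetId, condition, genes = NULL, cells = NULL) {
  if (!is.null(genes)) rownames(counts) <- genes
  if (!is.null(cells)) colnames(counts) <- cells
  if (!is(counts, "sparseMatrix")) {
    storage.mode(counts) <- "double"
    counts <- Matrix(counts, sparse = TRUE)
  }
  counts <- as(counts, "CsparseMatrix")
  sce <- SingleCellExperiment(assays = list(counts = counts))
  new("CountMatrix", sce, datasetId = as.character(datasetId),
      condition = as.character(condition))
}

#' @describeIn CountMatrix dataset identifier accessor
#' @param x a \code{CountMatrix}
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @rdname CountMatrix
#' @export
setMethod("datasetId", "CountMatrix", function(x) x@datasetId)

#' @describeIn CountMatrix cohort condition accessor
#' @export
setGeneric("cohortCondition", function(x) standardGeneric("cohortCondition"))

#' @rdname CountMatrix
#' @export
setMethod("cohortCondition", "CountMatrix", function(x) x@condition)

setMethod("show", "CountMatrix", function(object) {
  cat("CountMatrix:", nrow(object), "genes x", ncol(object), "cells\n")
  cat("  dataset:", object@datasetId, " condition:", object@condition, "\n")
  extra <- setdiff(assayNames(object), "counts")
  if (length(extra)) cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  if ("cluster" %in% colnames(colData(object)))
    cat("  clusters:", length(unique(object$cluster)), "\n")
})

#' Named gene-set collection
#'
#' Holds named gene sets (cell-type marker signatures or pathway sets), as
#' parsed from a GMT file. Gene identity is the bare symbol string,
#' case-sensitive.
#'
#' @slot sets named list of unique, non-empty character vectors.
#' @slot description one free-text description per set.
#' @export
setClass("SignatureDB",
  slots = c(sets = "list", description = "character")
)

setValidity("SignatureDB", function(object) {
  msg <- character()
  nm <- names(object@sets)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msg <- c(msg, "set names must be present and unique")
  if (length(object@description) != length(object@sets))
    msg <- c(msg, "one description per set is required")
  for (s in object@sets) {
    if (!is.character(s) || length(s) < 1L)
      msg <- c(msg, "every set must hold at least one gene symbol")
    else if (anyDuplicated(s))
      msg <- c(msg, "genes within a set must be unique")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' Construct a SignatureDB
#'
#' @param sets named list of character vectors (gene symbols).
#' @param description optional character vector of per-set descriptions.
#' @return a validated \linkS4class{SignatureDB}.
#' @examples
#' db <- SignatureDB(list(Tcell = c("CD3D", "CD3E"), Bcell = c("CD79A", "MS4A1")))
#' names(db); db[["Tcell"]]
#' @export
SignatureDB <- function(sets, description = NULL) {
  if (is.null(description)) description <- rep("", length(sets))
  new("SignatureDB", sets = sets, description = description)
}

#' @describeIn SignatureDB gene sets as a named list
#' @param x a \code{SignatureDB}
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname SignatureDB
#' @export
setMethod("geneSets", "SignatureDB", function(x) x@sets)

#' @rdname SignatureDB
#' @export
setMethod("names", "SignatureDB", function(x) names(x@sets))

#' @rdname SignatureDB
#' @export
setMethod("length", "SignatureDB", function(x) length(x@sets))

#' @rdname SignatureDB
#' @param i set name or index
#' @export
setMethod("[[", "SignatureDB", function(x, i) x@sets[[i]])

setMethod("show", "SignatureDB", function(object) {
  cat("SignatureDB with", length(object@sets), "gene sets\n")
  n <- head(names(object@sets), 5)
  sz <- vapply(object@sets[n], length, 1L)
  for (i in seq_along(n)) cat("  ", n[i], " (", sz[i], " genes)\n", sep = "")
  if (length(object@sets) > 5) cat("  ...\n")
})

#' Per-cell rank matrix over a merged gene union
#'
#' Houses the rank transform at the core of the cross-cohort differential
#' expression test: for one cell type, expression columns from all datasets
#' of both conditions are merged over the union of their top-gene lists
#' (m genes), and each cell's expression is converted to descending ranks
#' (highest expression = rank 1, midranks for ties among equal nonzero
#' values). Every gene with zero expression in a cell is unified to rank m
#' in that column, so absence carries a single well-defined rank.
#'
#' @slot genes length-m union gene list (name-sorted).
#' @slot ranks m x n matrix of per-cell ranks in [1, m].
#' @slot condition factor of length n with levels
#'   \code{c("metastatic", "primary")} assigning each cell to a cohort.
#' @slot nx number of metastatic cells.
#' @slot ny number of primary cells.
#' @seealso [buildRankMatrix()], [rankDeTest()]
#' @export
setClass("RankMatrix",
  slots = c(genes = "character", ranks = "matrix", condition = "factor",
            nx = "integer", ny = "integer")
)

setValidity("RankMatrix", function(object) {
  msg <- character()
  m <- length(object@genes)
  if (nrow(object@ranks) != m)
    msg <- c(msg, "ranks must have one row per union gene")
  if (length(object@condition) != ncol(object@ranks))
    msg <- c(msg, "one condition per column is required")
  if (!identical(levels(object@condition), c("metastatic", "primary")))
    msg <- c(msg, "condition levels must be c('metastatic', 'primary')")
  if (object@nx + object@ny != ncol(object@ranks))
    msg <- c(msg, "nx + ny must equal the number of cells")
  if (length(object@ranks) && (min(object@ranks) < 1 || max(object@ranks) > m))
    msg <- c(msg, "ranks must lie in [1, m]")
  if (length(msg)) msg else TRUE
})

#' @describeIn RankMatrix number of union genes (m)
#' @param x a \code{RankMatrix}
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname RankMatrix
#' @export
setMethod("nGenes", "RankMatrix", function(x) length(x@genes))

#' @describeIn RankMatrix the m x n rank matrix
#' @export
setGeneric("rankValues", function(x) standardGeneric("rankValues"))

#' @rdname RankMatrix
#' @export
setMethod("rankValues", "RankMatrix", function(x) x@ranks)

#' @describeIn RankMatrix per-cell condition factor
#' @export
setGeneric("cellCondition", function(x) standardGeneric("cellCondition"))

#' @rdname RankMatrix
#' @export
setMethod("cellCondition", "RankMatrix", function(x) x@condition)

setMethod("show", "RankMatrix", function(object) {
  cat("RankMatrix: m =", length(object@genes), "union genes, n =",
      ncol(object@ranks), "cells (nx =", object@nx, "metastatic, ny =",
      object@ny, "primary)\n")
})
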