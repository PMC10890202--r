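#' Read a single-cell count matrix
#'
#' Reads one dataset's gene-by-cell counts from either a 10x-style MTX
#' triplet bundle or a dense TSV (genes in rows, header line of barcodes).
#'
#' For \code{format = "mtx"}, \code{path} is the directory (or the
#' \code{matrix.mtx} file itself) of a bundle containing \code{matrix.mtx},
#' a features/genes file and a barcodes file. When the features file has two
#' or more columns, gene symbols are taken from the second column; otherwise
#' from the first.
#'
#' @param path file or bundle directory.
#' @param format \code{"mtx"} or \code{"tsv"}.
#' @param datasetId dataset identifier recorded on the result.
#' @param condition cohort condition (\code{"primary"} or \code{"metastatic"}).
#' @return a \linkS4class{CountMatrix}.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tc1\tc2", "g1\t1\t0", "g2\t2\t3"), tsv)
#' cm <- readCounts(tsv, "tsv", "toy", "primary")
#' @export
readCounts <- function(path, format = c("mtx", "tsv"), datasetId = "dataset",
                       condition = "primary") {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                             check.names = FALSE, comment.char = "")
    mat <- as.matrix(tab)
    if (any(is.na(mat)) || any(mat < 0) || any(mat != round(mat)))
      stop("non-count matrix: entries must be non-negative integers")
    return(CountMatrix(mat, datasetId, condition))
  }
  # mtx bundle
  dir <- if (dir.exists(path)) path else dirname(path)
  mtx <- file.path(dir, "matrix.mtx")
  feat <- .firstExisting(dir, c("features.tsv", "genes.tsv"))
  bc <- file.path(dir, "barcodes.tsv")
  if (!file.exists(mtx) || is.null(feat) || !file.exists(bc))
    stop("malformed 10x bundle: need matrix.mtx, features.tsv/genes.tsv and barcodes.tsv in ", dir)
  mat <- Matrix::readMM(mtx)
  if (any(mat@x < 0) || any(mat@x != round(mat@x)))
    stop("non-count matrix: entries must be non-negative integers")
  ft <- utils::read.table(feat, header = FALSE, sep = "\t", comment.char = "",
                          colClasses = "character")
  genes <- if (ncol(ft) >= 2) ft[[2]] else ft[[1]]
  cells <- readLines(bc)
  if (length(genes) != nrow(mat) || length(cells) != ncol(mat))
    stop("dimension mismatch: ", nrow(mat), "x", ncol(mat), " matrix vs ",
         length(genes), " genes, ", length(cells), " barcodes")
  CountMatrix(as(mat, "CsparseMatrix"), datasetId, condition,
              genes = genes, cells = cells)
}

.firstExisting <- function(dir, names) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Write a CountMatrix as a 10x-style MTX bundle
#'
#' Writes \code{matrix.mtx}, \code{features.tsv} (symbol in both columns)
#' and \code{barcodes.tsv} into \code{dir}. Round-trips through
#' [readCounts()] exactly.
#'
#' @param cm a \linkS4class{CountMatrix}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeCountsMtx <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(assay(cm, "counts"), file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(id = rownames(cm), symbol = rownames(cm)),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(cm), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a GMT gene-set file
#'
#' Each line is tab-separated: set name, description, then member genes.
#' Duplicate genes within a line are removed, keeping the first occurrence.
#'
#' @param path GMT file path.
#' @return a \linkS4class{SignatureDB}.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("malformed GMT line ", i, ": empty gene set")
    sets[[parts[1]]] <- genes
    descs <- c(descs, parts[2])
  }
  SignatureDB(sets, descs)
}

#' Write a SignatureDB to GMT
#'
#' @param db a \linkS4class{SignatureDB}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(db, path) {
  lines <- vapply(seq_along(db), function(i) {
    paste(c(names(db)[i], db@description[i], db[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Writes any stage's result data.frame with a header line, the data.frame's
#' column order, and floats rendered with 8 significant digits so a re-read
#' reproduces values to at least 6 significant digits.
#'
#' @param records a data.frame (possibly with zero rows).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTable <- function(records, path) {
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 8)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a result table written by writeTable
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
readTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    comment.char = "", stringsAsFactors = FALSE)
}

#' Read a cohort manifest
#'
#' A manifest is a TSV with columns \code{dataset_id}, \code{path},
#' \code{format} (\code{mtx} or \code{tsv}) and \code{condition}
#' (\code{primary} or \code{metastatic}). Relative paths are resolved
#' against the manifest's own directory.
#'
#' @param path manifest TSV path.
#' @param requireBoth require at least one dataset per condition (the
#'   two-condition comparison precondition).
#' @return a data.frame with the four columns, paths resolved.
#' @export
readManifest <- function(path, requireBoth = TRUE) {
  man <- readTable(path)
  need <- c("dataset_id", "path", "format", "condition")
  if (!all(need %in% colnames(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (!all(man$format %in% c("mtx", "tsv")))
    stop("manifest format must be 'mtx' or 'tsv'")
  if (!all(man$condition %in% VALID_CONDITIONS))
    stop("manifest condition must be 'primary' or 'metastatic'")
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  if (requireBoth && !all(VALID_CONDITIONS %in% man$condition))
    stop("manifest needs at least one dataset per condition")
  man
}

#' Read a ligand-receptor pair table
#'
#' @param path TSV with columns \code{ligand} and \code{receptor}.
#' @return data.frame of unique pairs.
#' @export
readLRPairs <- function(path) {
  tab <- readTable(path)
  if (!all(c("ligand", "receptor") %in% colnames(tab)))
    stop("pair table must have columns 'ligand' and 'receptor'")
  if (any(!nzchar(tab$ligand)) || any(!nzchar(tab$receptor)))
    stop("ligand and receptor symbols must be non-empty")
  tab <- unique(tab[, c("ligand", "receptor")])
  rownames(tab) <- NULL
  tab
}

# Stage logging: input dimensions, filter counts and seeds go to stderr and,
# when a log file is registered, to that file (no timestamps, so runs with
# the same seed produce byte-identical artifacts).
.logEnv <- new.env(parent = emptyenv())

#' Register a run-log file for stage messages
#'
#' @param path log file path, or \code{NULL} to disable file logging.
#' @return previous path, invisibly.
#' @export
setRunLog <- function(path) {
  old <- .logEnv$path
  .logEnv$path <- path
  if (!is.null(path) && !file.exists(path)) file.create(path)
  invisible(old)
}

stageLog <- function(...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(.logEnv$path)) cat(msg, "\n", file = .logEnv$path, append = TRUE)
  invisible(msg)
}
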