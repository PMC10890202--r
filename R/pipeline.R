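#' Deterministic per-stage seed derivation
#'
#' Fans a single run seed out to stage-specific seeds via a fixed string
#' hash, so every stage is independently reproducible.
#'
#' @param seed global run seed.
#' @param stage stage name.
#' @return an integer seed below 2^31.
#' @export
stageSeed <- function(seed, stage) {
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 2147483647
  as.integer((h * 31 + as.integer(seed)) %% 2147483647)
}

#' Full-run configuration
#'
#' Collects the file inputs and every stage's thresholds for [runAll()].
#'
#' @param manifest cohort manifest TSV path (see [readManifest()]).
#' @param markersGmt GMT of cell-type marker signatures.
#' @param pathwaysGmt GMT of proliferation pathway sets.
#' @param termsGmt GMT of over-representation term sets.
#' @param lrPairs ligand-receptor pair TSV.
#' @param outDir run directory for stage artifacts.
#' @param seed global seed, fanned out per stage via [stageSeed()].
#' @param qc a [qcThresholds()] object.
#' @param targetSize normalization library size.
#' @param hvgN highly-variable-gene count.
#' @param nPcs,k,resolution clustering parameters.
#' @param annotPerm NES permutations; \code{topFraction} AUCell window.
#' @param topFraction AUCell recovery-window fraction.
#' @param topK per-dataset top-gene list size for the rank DE.
#' @param fcBounds,deAlpha rank-DE significance parameters.
#' @param ctPerm,minFrac,ctAlpha crosstalk parameters.
#' @param weightExponent,rMin,prolifAlpha proliferation-screen parameters.
#' @param oraAlpha over-representation significance level.
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(manifest, markersGmt, pathwaysGmt, termsGmt, lrPairs,
                      outDir, seed = 1, qc = qcThresholds(),
                      targetSize = 1e4, hvgN = 2000, nPcs = 30, k = 20,
                      resolution = 0.8, annotPerm = 1000, topFraction = 0.05,
                      topK = 5000, fcBounds = c(0.8, 1.25), deAlpha = 0.05,
                      ctPerm = 1000, minFrac = 0.1, ctAlpha = 0.05,
                      weightExponent = 0.25, rMin = 0.3, prolifAlpha = 0.05,
                      oraAlpha = 0.05) {
  cfg <- as.list(environment())
  class(cfg) <- "RunConfig"
  cfg
}

#' Cell types shared by both cohorts
#'
#' @param annotations named list with elements \code{primary} and
#'   \code{metastatic}, each a vector of final cell-type calls.
#' @return name-sorted intersection, excluding \code{"unassigned"}.
#' @export
sharedTypes <- function(annotations) {
  shared <- sort(Reduce(intersect, lapply(annotations, unique)))
  shared <- setdiff(shared, "unassigned")
  if (!length(shared)) warning("no cell types shared across cohorts")
  shared
}

#' Cross-cohort cell-type proportion table
#'
#' @param typeLabels per-cell type labels, one vector per dataset.
#' @param conditions condition per dataset.
#' @return data.frame with a \code{type} column and one pooled-fraction
#'   column per condition; fractions per column sum to 1 and absent types
#'   carry 0.
#' @export
proportionTable <- function(typeLabels, conditions) {
  types <- sort(unique(unlist(typeLabels)))
  out <- data.frame(type = types)
  for (cond in unique(conditions)) {
    pooled <- unlist(typeLabels[conditions == cond])
    out[[cond]] <- as.vector(table(factor(pooled, levels = types))) /
      length(pooled)
  }
  out
}

.runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full two-cohort comparison
#'
#' Executes QC, normalization, per-dataset clustering and ensemble
#' annotation, then rank-based DE on every shared cell type, the
#' ligand-receptor permutation test per cohort, the proliferation scoring
#' and driver screen per cohort, and over-representation analysis of the
#' resulting gene lists. Per-stage artifacts are written under
#' \code{config$outDir} as they are produced, together with five summary
#' tables (cell-type proportions, per-type up/down DE counts, interaction
#' shares, driver counts) and a markdown digest. Deterministic for a fixed
#' seed; any stage error aborts with the stage name, keeping prior outputs.
#'
#' @param config a [runConfig()].
#' @return (invisibly) a list with the in-memory stage results and the run
#'   directory.
#' @export
runAll <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  for (f in c(config$manifest, config$markersGmt, config$pathwaysGmt,
              config$termsGmt, config$lrPairs))
    if (!file.exists(f)) stop("input file missing: ", f)
  man <- readManifest(config$manifest)
  for (i in seq_len(nrow(man)))
    if (!file.exists(man$path[i]) && !dir.exists(man$path[i]))
      stop("manifest references a missing file: ", man$path[i])
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  setRunLog(file.path(config$outDir, "run.log"))
  on.exit(setRunLog(NULL))
  stageLog("run-all: ", nrow(man), " datasets, seed ", config$seed)

  markerDB <- readGmt(config$markersGmt)
  pathwayDB <- readGmt(config$pathwaysGmt)
  termDB <- readGmt(config$termsGmt)
  lrPairs <- readLRPairs(config$lrPairs)

  datasets <- list(); typeLabels <- list(); annos <- list()
  .runStage("qc+cluster+annotate", {
    for (i in seq_len(nrow(man))) {
      id <- man$dataset_id[i]
      cm <- readCounts(man$path[i], man$format[i], id, man$condition[i])
      cm <- qcFilter(cm, config$qc)
      cm <- normalizeLog(cm, config$targetSize)
      hvg <- selectHvg(cm, config$hvgN)
      cm <- embedCluster(cm, hvg, nPcs = config$nPcs, k = config$k,
                         resolution = config$resolution,
                         seed = stageSeed(config$seed, paste0("cluster:", id)))
      ann <- ensembleAnnotate(cm, markerDB, nPerm = config$annotPerm,
                              seed = stageSeed(config$seed, paste0("annotate:", id)),
                              topFraction = config$topFraction)
      writeTable(data.frame(barcode = colnames(cm), dataset_id = id,
                            cluster = cm$cluster),
                 file.path(config$outDir, paste0("clusters_", id, ".tsv")))
      writeTable(ann, file.path(config$outDir, paste0("annotation_", id, ".tsv")))
      datasets[[id]] <- cm
      annos[[id]] <- ann
      typeLabels[[id]] <- annotateCells(cm, ann)
    }
  })
  conds <- man$condition
  names(conds) <- man$dataset_id

  props <- .runStage("proportions", {
    p <- proportionTable(typeLabels, conds)
    writeTable(p, file.path(config$outDir, "proportions.tsv"))
    perDs <- proportionTable(typeLabels, names(typeLabels))
    writeTable(perDs, file.path(config$outDir, "proportions_per_dataset.tsv"))
    p
  })

  byCond <- split(names(typeLabels), conds[names(typeLabels)])
  shared <- sharedTypes(lapply(byCond, function(ids)
    unlist(typeLabels[ids], use.names = FALSE)))

  deResults <- list(); deCounts <- NULL
  .runStage("rank-de", {
    rows <- list()
    for (ty in shared) {
      de <- rankDeForType(datasets, typeLabels, ty, topK = config$topK,
                          fcBounds = config$fcBounds, alpha = config$deAlpha)
      writeTable(de, file.path(config$outDir,
                               paste0("rankde_", gsub("[^A-Za-z0-9]", "_", ty), ".tsv")))
      deResults[[ty]] <- de
      rows[[ty]] <- data.frame(type = ty,
                               up_in_metastatic = sum(de$direction == "up_in_metastatic"),
                               down_in_metastatic = sum(de$direction == "down_in_metastatic"))
    }
    deCounts <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
                 else data.frame(type = character(), up_in_metastatic = integer(),
                                 down_in_metastatic = integer())
    writeTable(deCounts, file.path(config$outDir, "de_counts.tsv"))
  })

  pooled <- list()
  for (cond in names(byCond)) {
    ids <- byCond[[cond]]
    common <- Reduce(intersect, lapply(datasets[ids], rownames))
    mats <- lapply(ids, function(id)
      as.matrix(assay(datasets[[id]], "lognorm")[common, , drop = FALSE]))
    lab <- unlist(typeLabels[ids], use.names = FALSE)
    keep <- lab != "unassigned"
    pooled[[cond]] <- list(x = do.call(cbind, mats)[, keep, drop = FALSE],
                           labels = lab[keep])
  }

  ctResults <- list(); shares <- NULL
  .runStage("crosstalk", {
    for (cond in names(pooled)) {
      ct <- interactionTest(pooled[[cond]]$x, pooled[[cond]]$labels, lrPairs,
                            nPerm = config$ctPerm,
                            seed = stageSeed(config$seed, paste0("crosstalk:", cond)),
                            minFrac = config$minFrac, alpha = config$ctAlpha)
      writeTable(ct, file.path(config$outDir, paste0("interactions_", cond, ".tsv")))
      ctResults[[cond]] <- ct
    }
    shares <- interactionShare(ctResults)
    writeTable(shares, file.path(config$outDir, "interaction_shares.tsv"))
  })

  prolif <- list(); driverCounts <- NULL
  .runStage("proliferation", {
    rows <- list()
    for (cond in names(pooled)) {
      x <- pooled[[cond]]$x
      scoreTab <- pathwayScores(x, pathwayDB, config$weightExponent)
      writeTable(scoreTab, file.path(config$outDir,
                                     paste0("pathway_scores_", cond, ".tsv")))
      drivers <- list()
      for (pw in names(pathwayDB)) {
        sc <- scoreTab$score[scoreTab$pathway == pw]
        dr <- driverScreen(x, sc, rMin = config$rMin, alpha = config$prolifAlpha)
        dr$pathway <- pw
        drivers[[pw]] <- dr
        rows[[paste(cond, pw)]] <- data.frame(condition = cond, pathway = pw,
                                              n_drivers = sum(dr$selected))
      }
      allDr <- do.call(rbind, c(drivers, list(make.row.names = FALSE)))
      writeTable(allDr, file.path(config$outDir, paste0("drivers_", cond, ".tsv")))
      sel <- sort(unique(allDr$gene[allDr$selected]))
      rows[[paste(cond, "union")]] <- data.frame(condition = cond,
                                                 pathway = "union",
                                                 n_drivers = length(sel))
      prolif[[cond]] <- list(scores = scoreTab, drivers = allDr, union = sel)
    }
    driverCounts <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    writeTable(driverCounts, file.path(config$outDir, "driver_counts.tsv"))
  })

  enrichments <- list()
  .runStage("enrich", {
    universe <- sort(unique(unlist(lapply(datasets, rownames))))
    for (ty in names(deResults)) {
      de <- deResults[[ty]]
      for (dir in c("up_in_metastatic", "down_in_metastatic")) {
        genes <- de$gene[de$direction == dir]
        if (!length(genes)) next
        key <- paste0(gsub("[^A-Za-z0-9]", "_", ty), "_", sub("_in_metastatic", "", dir))
        er <- ora(genes, termDB, universe, config$oraAlpha)
        writeTable(er, file.path(config$outDir, paste0("ora_", key, ".tsv")))
        enrichments[[key]] <- er
      }
    }
    for (cond in names(prolif)) {
      sel <- prolif[[cond]]$union
      if (length(sel)) {
        er <- ora(sel, termDB, universe, config$oraAlpha)
        writeTable(er, file.path(config$outDir, paste0("ora_drivers_", cond, ".tsv")))
        enrichments[[paste0("drivers_", cond)]] <- er
      }
    }
  })

  digest <- c("# Run summary", "",
              paste0("Datasets: ", nrow(man), " (",
                     sum(conds == "metastatic"), " metastatic, ",
                     sum(conds == "primary"), " primary)"),
              paste0("Cell types: ", nrow(props), "; shared: ",
                     length(shared), " (", paste(shared, collapse = ", "), ")"),
              paste0("DE calls (up/down in metastatic): ",
                     sum(deCounts$up_in_metastatic), "/",
                     sum(deCounts$down_in_metastatic)),
              paste0("Significant interactions: ",
                     paste(vapply(names(ctResults), function(nm)
                       paste0(nm, " = ", sum(ctResults[[nm]]$significant)),
                       character(1)), collapse = ", ")),
              paste0("Driver genes (union): ",
                     paste(vapply(names(prolif), function(nm)
                       paste0(nm, " = ", length(prolif[[nm]]$union)),
                       character(1)), collapse = ", ")))
  writeLines(digest, file.path(config$outDir, "summary.md"))

  invisible(list(outDir = config$outDir, manifest = man, datasets = datasets,
                 annotations = annos, typeLabels = typeLabels,
                 proportions = props, shared = shared, de = deResults,
                 deCounts = deCounts, crosstalk = ctResults, shares = shares,
                 proliferation = prolif, driverCounts = driverCounts,
                 enrichments = enrichments))
}
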