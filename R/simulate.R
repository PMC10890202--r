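#' Synthetic multi-dataset cohort configuration
#'
#' Builds the configuration for [simulateCohort()]. The generator emulates a
#' two-condition comparison (several datasets per condition) with the
#' statistical structure every downstream stage assumes: cell-type marker
#' structure, per-(dataset, gene) multiplicative batch factors,
#' condition-specific differential expression within shared cell types,
#' jointly boosted ligand-receptor genes in sender/receiver types, and a
#' latent per-cell proliferation activity that drives both pathway genes and
#' correlated driver genes.
#'
#' @param nDatasetsPerCondition datasets per condition.
#' @param cellsPerDataset cells per dataset.
#' @param nGenes total genes; symbols are \code{g0001..}.
#' @param cellTypes list of \code{list(name, proportion, markers, boost)}
#'   where \code{boost} is the marker log-fold boost in that type.
#' @param deSpec data.frame with columns \code{cell_type}, \code{gene},
#'   \code{higher_in} (condition with higher expression) and \code{log2fc}.
#' @param lrSpec data.frame with columns \code{ligand}, \code{receptor},
#'   \code{sender}, \code{receiver}; both genes are boosted (log-scale
#'   \code{lrBoost}) in their respective types.
#' @param prolifSpec list with \code{pathways} (named list of gene vectors),
#'   \code{drivers} (genes), \code{rho} (target driver/latent-activity
#'   Pearson correlation, in (0,1)) and \code{pathwayLoading} (log-scale
#'   loading of the latent activity on pathway genes).
#' @param lrBoost log-scale expression boost for planted ligand/receptor
#'   genes in their sender/receiver types.
#' @param nbDispersion negative-binomial size parameter (\code{Inf} gives
#'   Poisson counts).
#' @param dropoutRate probability in \code{[0, 1)} of zeroing each count.
#' @param batchScaleSd sd of the per-(dataset, gene) log-normal batch factor.
#' @param seed RNG seed; fixed seed and config give byte-identical cohorts.
#' @return a \code{SimConfig} list.
#' @seealso [defaultSimConfig()] for the standard study conditions.
#' @export
simConfig <- function(nDatasetsPerCondition = 2, cellsPerDataset = 600,
                      nGenes = 1000, cellTypes, deSpec = NULL, lrSpec = NULL,
                      prolifSpec = NULL, lrBoost = log(8), nbDispersion = 2,
                      dropoutRate = 0.05, batchScaleSd = 0.08, seed = 1) {
  cfg <- list(nDatasetsPerCondition = as.integer(nDatasetsPerCondition),
              cellsPerDataset = as.integer(cellsPerDataset),
              nGenes = as.integer(nGenes), cellTypes = cellTypes,
              deSpec = deSpec, lrSpec = lrSpec, prolifSpec = prolifSpec,
              lrBoost = lrBoost, nbDispersion = nbDispersion,
              dropoutRate = dropoutRate, batchScaleSd = batchScaleSd,
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

#' Validate a SimConfig
#'
#' @param cfg a \code{SimConfig}.
#' @return \code{TRUE} invisibly; otherwise an error.
#' @export
validateSimConfig <- function(cfg) {
  genes <- sprintf("g%04d", seq_len(cfg$nGenes))
  props <- vapply(cfg$cellTypes, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-9)
    stop("cell-type proportions must sum to 1")
  named <- c(unlist(lapply(cfg$cellTypes, `[[`, "markers")),
             cfg$deSpec$gene, cfg$lrSpec$ligand, cfg$lrSpec$receptor,
             unlist(cfg$prolifSpec$pathways), cfg$prolifSpec$drivers)
  bad <- setdiff(named, genes)
  if (length(bad))
    stop("named genes not in the gene panel: ", paste(head(bad, 5), collapse = ", "))
  if (!is.null(cfg$prolifSpec)) {
    rho <- cfg$prolifSpec$rho
    if (!is.numeric(rho) || rho <= 0 || rho >= 1)
      stop("prolifSpec$rho must lie in (0, 1)")
  }
  if (cfg$dropoutRate < 0 || cfg$dropoutRate >= 1)
    stop("dropoutRate must lie in [0, 1)")
  if (cfg$batchScaleSd < 0) stop("batchScaleSd must be >= 0")
  tn <- vapply(cfg$cellTypes, `[[`, character(1), "name")
  if (!is.null(cfg$deSpec) && !all(cfg$deSpec$cell_type %in% tn))
    stop("deSpec cell types must be among the configured types")
  if (!is.null(cfg$lrSpec) &&
      !all(c(cfg$lrSpec$sender, cfg$lrSpec$receiver) %in% tn))
    stop("lrSpec sender/receiver types must be among the configured types")
  invisible(TRUE)
}

#' Standard synthetic study conditions
#'
#' The default cohort: two datasets per condition, four cell types
#' (T cell, B cell, hepatocyte, macrophage) with 25 markers each boosted
#' 8-fold, 20 condition-specific DE genes (|log2FC| = 2) in T cells, three
#' planted ligand-receptor interactions, and a proliferation program of two
#' 20-gene pathway sets plus 50 driver genes at target correlation 0.5.
#'
#' @param seed RNG seed.
#' @param deSpec,lrSpec,prolifSpec optional overrides of the canned planted
#'   structure described above.
#' @param ... further overrides passed to [simConfig()].
#' @return a \code{SimConfig}.
#' @export
defaultSimConfig <- function(seed = 1, deSpec, lrSpec, prolifSpec, ...) {
  g <- function(i) sprintf("g%04d", i)
  cellTypes <- list(
    list(name = "Tcell",      proportion = 0.35, markers = g(1:25),   boost = log(8)),
    list(name = "Bcell",      proportion = 0.25, markers = g(26:50),  boost = log(8)),
    list(name = "Hepatocyte", proportion = 0.25, markers = g(51:75),  boost = log(8)),
    list(name = "Macrophage", proportion = 0.15, markers = g(76:100), boost = log(8)))
  if (missing(deSpec)) deSpec <- data.frame(
    cell_type = "Tcell",
    gene = g(101:120),
    higher_in = rep(c("metastatic", "primary"), each = 10),
    log2fc = 2)
  if (missing(lrSpec)) lrSpec <- data.frame(
    ligand = g(c(201, 203, 205)), receptor = g(c(202, 204, 206)),
    sender = c("Tcell", "Macrophage", "Hepatocyte"),
    receiver = c("Hepatocyte", "Bcell", "Tcell"))
  if (missing(prolifSpec)) prolifSpec <- list(
    pathways = list(DNA_REPLICATION = g(301:320), CELL_CYCLE = g(321:340)),
    drivers = g(401:450), rho = 0.5, pathwayLoading = 0.6)
  simConfig(cellTypes = cellTypes, deSpec = deSpec, lrSpec = lrSpec,
            prolifSpec = prolifSpec, seed = seed, ...)
}

# Latent-activity loading for a driver gene so that the Pearson correlation
# between observed log-scale expression and the N(0,1) activity is ~rho.
# Works on the exact zero-inflated NB pmf: the local slope c of
# E[log1p(f*X)] in log-mean and the noise variance v of log1p(f*X) give
# cor = c*s / sqrt(c^2 s^2 + v), solved for s. f approximates the typical
# library-size normalization factor.
.driverLoading <- function(mu, size, dropout, rho, f = 10) {
  finiteSize <- is.finite(size)
  top <- if (finiteSize) stats::qnbinom(1 - 1e-8, size = size, mu = mu * 3)
         else stats::qpois(1 - 1e-8, lambda = mu * 3)
  xs <- 0:max(30, top)
  y <- log1p(f * xs)
  pmfAt <- function(lm) {
    pm <- if (finiteSize) stats::dnbinom(xs, size = size, mu = exp(lm))
          else stats::dpois(xs, lambda = exp(lm))
    pm <- (1 - dropout) * pm
    pm[1] <- pm[1] + dropout
    pm
  }
  h <- 0.05
  slope <- (sum(pmfAt(log(mu) + h) * y) - sum(pmfAt(log(mu) - h) * y)) / (2 * h)
  pm <- pmfAt(log(mu))
  v <- sum(pm * y^2) - sum(pm * y)^2
  rho * sqrt(v) / (slope * sqrt(1 - rho^2))
}

#' Simulate a multi-dataset two-condition cohort
#'
#' Draws, for each dataset: a per-cell type from the configured proportions;
#' log-normal baseline per-gene means (planted genes floored at mean 2 so
#' structure sits on expressed genes); marker boosts in their own type;
#' condition-specific DE effects; a per-(dataset, gene) multiplicative batch
#' factor; ligand/receptor boosts in sender/receiver types; and a latent
#' per-cell N(0,1) proliferation activity loading on pathway and driver
#' genes (the driver loading is calibrated on the exact count measurement
#' model so the log-expression/activity Pearson correlation is
#' approximately \code{rho}). Counts
#' are negative-binomial (Poisson when \code{nbDispersion = Inf}) and then
#' zeroed with probability \code{dropoutRate}.
#'
#' @param config a \code{SimConfig}.
#' @return a list with \code{datasets} (list of \linkS4class{CountMatrix}),
#'   \code{truth} (cells / de / interactions / drivers tables), and
#'   \code{markerDB}, \code{pathwayDB}, \code{termDB}
#'   (\linkS4class{SignatureDB} objects), plus \code{lrPairs}.
#' @examples
#' cohort <- simulateCohort(defaultSimConfig(seed = 7, cellsPerDataset = 100))
#' length(cohort$datasets)
#' @export
simulateCohort <- function(config) {
  validateSimConfig(config)
  set.seed(config$seed)
  G <- config$nGenes
  genes <- sprintf("g%04d", seq_len(G))
  typeNames <- vapply(config$cellTypes, `[[`, character(1), "name")
  props <- vapply(config$cellTypes, `[[`, numeric(1), "proportion")

  planted <- unique(c(unlist(lapply(config$cellTypes, `[[`, "markers")),
                      config$deSpec$gene, config$lrSpec$ligand,
                      config$lrSpec$receptor,
                      unlist(config$prolifSpec$pathways),
                      config$prolifSpec$drivers))
  baseMu <- exp(stats::rnorm(G, log(0.3), 1.0))
  names(baseMu) <- genes
  baseMu[planted] <- pmax(baseMu[planted], 2)

  # log-scale boost of gene g in type t (markers, ligand/receptor genes)
  typeBoost <- matrix(0, G, length(typeNames), dimnames = list(genes, typeNames))
  for (ct in config$cellTypes)
    typeBoost[ct$markers, ct$name] <- typeBoost[ct$markers, ct$name] + ct$boost
  if (!is.null(config$lrSpec)) {
    for (i in seq_len(nrow(config$lrSpec))) {
      lr <- config$lrSpec[i, ]
      typeBoost[lr$ligand, lr$sender] <- typeBoost[lr$ligand, lr$sender] + config$lrBoost
      typeBoost[lr$receptor, lr$receiver] <- typeBoost[lr$receptor, lr$receiver] + config$lrBoost
    }
  }

  # condition-specific DE effect of gene g in type t, applied in `higher_in`
  deBoost <- list(metastatic = matrix(0, G, length(typeNames),
                                      dimnames = list(genes, typeNames)),
                  primary = matrix(0, G, length(typeNames),
                                   dimnames = list(genes, typeNames)))
  if (!is.null(config$deSpec)) {
    for (i in seq_len(nrow(config$deSpec))) {
      de <- config$deSpec[i, ]
      deBoost[[de$higher_in]][de$gene, de$cell_type] <-
        deBoost[[de$higher_in]][de$gene, de$cell_type] + log(2) * de$log2fc
    }
  }

  # latent-activity loadings: fixed for pathway genes; driver loadings are
  # calibrated against the count measurement model so that the observed
  # log-expression / activity Pearson correlation is approximately rho
  loading <- stats::setNames(numeric(G), genes)
  if (!is.null(config$prolifSpec)) {
    ps <- config$prolifSpec
    loading[unlist(ps$pathways)] <- ps$pathwayLoading
    loading[ps$drivers] <- vapply(baseMu[ps$drivers], .driverLoading,
                                  numeric(1), size = config$nbDispersion,
                                  dropout = config$dropoutRate, rho = ps$rho)
  }

  datasets <- list()
  cellRows <- list()
  for (cond in c("metastatic", "primary")) {
    for (d in seq_len(config$nDatasetsPerCondition)) {
      dsId <- sprintf("%s_%d", cond, d)
      C <- config$cellsPerDataset
      batch <- exp(stats::rnorm(G, 0, config$batchScaleSd))
      types <- sample(typeNames, C, replace = TRUE, prob = props)
      activity <- stats::rnorm(C)
      logMu <- matrix(log(baseMu * batch), G, C) +
        typeBoost[, types, drop = FALSE] +
        deBoost[[cond]][, types, drop = FALSE] +
        outer(loading, activity)
      mu <- exp(logMu)
      cnt <- if (is.finite(config$nbDispersion))
        stats::rnbinom(G * C, size = config$nbDispersion, mu = mu)
      else stats::rpois(G * C, lambda = mu)
      if (config$dropoutRate > 0)
        cnt[stats::runif(G * C) < config$dropoutRate] <- 0L
      m <- matrix(as.double(cnt), G, C,
                  dimnames = list(genes, sprintf("%s_c%04d", dsId, seq_len(C))))
      datasets[[dsId]] <- CountMatrix(m, dsId, cond)
      cellRows[[dsId]] <- data.frame(barcode = colnames(m), dataset_id = dsId,
                                     condition = cond, cell_type = types,
                                     activity = activity)
    }
  }

  markerSets <- stats::setNames(lapply(config$cellTypes, `[[`, "markers"),
                                typeNames)
  markerSets <- markerSets[vapply(markerSets, length, 1L) > 0]
  markerDB <- if (length(markerSets)) SignatureDB(markerSets) else NULL
  pathwayDB <- if (!is.null(config$prolifSpec))
    SignatureDB(config$prolifSpec$pathways) else NULL
  # toy term collection for over-representation: planted sets plus random ones
  rndSets <- lapply(1:4, function(i) sort(sample(genes, 30)))
  names(rndSets) <- paste0("RANDOM_SET_", 1:4)
  termDB <- SignatureDB(c(if (!is.null(markerDB)) geneSets(markerDB),
                          if (!is.null(pathwayDB)) geneSets(pathwayDB),
                          rndSets))

  truth <- list(
    cells = do.call(rbind, c(cellRows, list(make.row.names = FALSE))),
    de = if (is.null(config$deSpec))
      data.frame(cell_type = character(), gene = character(),
                 higher_in = character(), log2fc = numeric())
    else config$deSpec,
    interactions = if (is.null(config$lrSpec))
      data.frame(ligand = character(), receptor = character(),
                 sender = character(), receiver = character())
    else config$lrSpec,
    drivers = if (is.null(config$prolifSpec))
      data.frame(gene = character(), rho = numeric())
    else data.frame(gene = config$prolifSpec$drivers,
                    rho = config$prolifSpec$rho))

  list(datasets = datasets, truth = truth, markerDB = markerDB,
       pathwayDB = pathwayDB, termDB = termDB, lrPairs = config$lrSpec,
       config = config)
}

#' Write machine-readable truth tables for a simulated cohort
#'
#' Emits the cell-to-type, DE, interaction and driver truth tables the test
#' suite consumes.
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory.
#' @return paths of the written tables, invisibly.
#' @export
truthReport <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cells = file.path(dir, "truth_cells.tsv"),
             de = file.path(dir, "truth_de.tsv"),
             interactions = file.path(dir, "truth_interactions.tsv"),
             drivers = file.path(dir, "truth_drivers.tsv"))
  writeTable(cohort$truth$cells, paths["cells"])
  writeTable(cohort$truth$de, paths["de"])
  writeTable(cohort$truth$interactions, paths["interactions"])
  writeTable(cohort$truth$drivers, paths["drivers"])
  invisible(paths)
}

#' Write a simulated cohort to disk as pipeline inputs
#'
#' Writes one MTX bundle per dataset, a cohort manifest, marker / pathway /
#' term GMT files, the ligand-receptor pair table, and the truth tables —
#' everything [runAll()] needs.
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(dataset_id = character(), path = character(),
                    format = character(), condition = character())
  for (cm in cohort$datasets) {
    sub <- file.path(dir, datasetId(cm))
    writeCountsMtx(cm, sub)
    man <- rbind(man, data.frame(dataset_id = datasetId(cm),
                                 path = datasetId(cm), format = "mtx",
                                 condition = cohortCondition(cm)))
  }
  writeTable(man, file.path(dir, "manifest.tsv"))
  writeGmt(cohort$markerDB, file.path(dir, "markers.gmt"))
  if (!is.null(cohort$pathwayDB))
    writeGmt(cohort$pathwayDB, file.path(dir, "pathways.gmt"))
  writeGmt(cohort$termDB, file.path(dir, "terms.gmt"))
  if (!is.null(cohort$lrPairs))
    writeTable(cohort$lrPairs[, c("ligand", "receptor")],
               file.path(dir, "lr_pairs.tsv"))
  truthReport(cohort, dir)
  invisible(file.path(dir, "manifest.tsv"))
}
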