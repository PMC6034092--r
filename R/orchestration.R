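#' Read a samples-by-features dataset from delimited files
#'
#' The matrix file is delimiter-separated with a header row of feature ids and
#' samples in rows. Labels are either a designated column of the matrix file
#' (\code{labelColumn}) or a separate single-column file (\code{labelsFile});
#' they must be in {0, 1}.
#'
#' @param matrixFile path to the feature matrix.
#' @param labelsFile path to a single-column label file.
#' @param labelColumn name of a matrix column holding the labels.
#' @param sep field separator (default tab).
#' @return list with elements \code{x} (numeric matrix) and \code{y}
#'   (integer labels)
#' @export
readDataset <- function(matrixFile, labelsFile = NULL, labelColumn = NULL,
                        sep = "\t") {
  if (!file.exists(matrixFile)) stop("matrix file not found: ", matrixFile)
  tab <- utils::read.delim(matrixFile, header = TRUE, sep = sep,
                           check.names = FALSE)
  if (!is.null(labelColumn)) {
    if (!labelColumn %in% colnames(tab))
      stop("label column not found: ", labelColumn)
    y <- as.integer(tab[[labelColumn]])
    tab <- tab[, setdiff(colnames(tab), labelColumn), drop = FALSE]
  } else if (!is.null(labelsFile)) {
    if (!file.exists(labelsFile)) stop("labels file not found: ", labelsFile)
    y <- as.integer(readLines(labelsFile))
  } else stop("either labelsFile or labelColumn is required")
  x <- as.matrix(tab)
  storage.mode(x) <- "double"
  if (anyNA(y) || !all(y %in% c(0L, 1L))) stop("labels must be {0,1}")
  list(x = x, y = y)
}

#' Fit, aggregate and rank: one reproducible ranking run
#'
#' Fits a forest, computes MDI importances, aggregates them over the
#' partition and ranks the groups. When \code{outDir} is given, writes the
#' score table (\code{scores.tsv}) and a JSON metadata file with all
#' parameters and the seed, sufficient to reproduce the run.
#'
#' @param x,y data matrix and binary labels (or use \code{matrixFile} etc.
#'   via [readDataset()] beforehand).
#' @param partition a [FeaturePartition-class].
#' @param aggregation \code{"sum"}, \code{"avg"} or \code{"max"}.
#' @param trees,k,bootstrap,seed forest parameters, see [groupForest()].
#' @param outDir optional output directory.
#' @return the [GroupScoreTable-class]
#' @export
runRank <- function(x, y, partition, aggregation = "avg", trees = 1000L,
                    k = "sqrt", bootstrap = TRUE, seed = 1L, outDir = NULL) {
  forest <- groupForest(x, y, ntree = trees, k = k, bootstrap = bootstrap,
                        seed = seed)
  table <- aggregateImportance(mdiImportance(forest), partition, aggregation)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeGroupScores(table, file.path(outDir, "scores.tsv"))
    jsonlite::write_json(
      list(aggregation = aggregation, trees = trees, k = k,
           bootstrap = bootstrap, seed = seed, n = nrow(x), p = ncol(x),
           groups = nGroups(partition),
           package_version = as.character(utils::packageVersion("groupRF"))),
      file.path(outDir, "run.meta.json"), auto_unbox = TRUE, null = "null")
  }
  table
}

#' Run the synthetic benchmark over a grid of conditions
#'
#' For every grid cell (combination of number of relevant groups, sample
#' size, K, aggregation and selection method) generates \code{nDatasets}
#' synthetic datasets (see [syntheticBenchmark()]), runs ranking + selection +
#' evaluation, and returns per-dataset metrics plus per-cell means.
#' Per-dataset seeds derive deterministically from the cell index and the
#' dataset index, so interrupted grids re-run identically.
#'
#' @param grid data.frame with columns \code{nRelevant}, \code{n}, \code{k},
#'   \code{aggregation}, \code{method} (any of cer/cerr/efdr/mprobes).
#' @param nDatasets datasets per cell.
#' @param p,g generator dimensions.
#' @param trees,nPerm,alpha,rule selection protocol, see [groupSelect()].
#' @param seed master seed.
#' @param outDir optional directory for \code{results.tsv} /
#'   \code{results_mean.tsv} and run metadata.
#' @param verbose report progress.
#' @return list with data.frames \code{perDataset} and \code{means}
#' @export
runBenchmark <- function(grid, nDatasets = 20L, p = 500L, g = 50L,
                         trees = 1000L, nPerm = 1000L, alpha = 0.05,
                         rule = "first_crossing", seed = 1L, outDir = NULL,
                         verbose = FALSE) {
  needed <- c("nRelevant", "n", "k", "aggregation", "method")
  if (!all(needed %in% colnames(grid)))
    stop("grid must have columns: ", paste(needed, collapse = ", "))
  rows <- list()
  for (cell in seq_len(nrow(grid))) {
    for (d in seq_len(nDatasets)) {
      dseed <- .deriveSeed(seed, cell, d)
      bench <- syntheticBenchmark(n = grid$n[cell], p = p, g = g,
                                  nRelevant = grid$nRelevant[cell],
                                  seed = dseed)
      if (verbose) message("cell ", cell, " dataset ", d)
      kc <- as.character(grid$k[cell])
      kval <- if (kc %in% c("sqrt", "all")) kc else as.integer(kc)
      res <- groupSelect(bench@x, bench@y, bench@partition,
                         methods = as.character(grid$method[cell]),
                         aggregation = as.character(grid$aggregation[cell]),
                         nPerm = nPerm, alpha = alpha, trees = trees,
                         k = kval, seed = dseed, rule = rule)
      metrics <- assessSelection(selectedGroups(res), groupRanking(res@table),
                                 bench@relevantGroups)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(cell = cell, dataset = d, seed = dseed,
                   nRelevant = grid$nRelevant[cell], n = grid$n[cell],
                   k = as.character(grid$k[cell]),
                   aggregation = as.character(grid$aggregation[cell]),
                   method = as.character(grid$method[cell])),
        metrics)
    }
  }
  perDataset <- do.call(rbind, rows)
  num <- c("precision", "recall", "aupr", "rec1", "prec1", "n_selected",
           "n_relevant_selected")
  means <- do.call(rbind, lapply(split(perDataset, perDataset$cell),
    function(df) cbind(df[1, c("cell", "nRelevant", "n", "k", "aggregation",
                               "method")],
                       as.data.frame(as.list(colMeans(df[, num]))))))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(perDataset, file.path(outDir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(means, file.path(outDir, "results_mean.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(seed = seed, nDatasets = nDatasets, p = p,
                              g = g, trees = trees, nPerm = nPerm,
                              alpha = alpha, rule = rule),
                         file.path(outDir, "benchmark.meta.json"),
                         auto_unbox = TRUE, null = "null")
  }
  list(perDataset = perDataset, means = means)
}
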