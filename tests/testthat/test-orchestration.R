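test_that("readDataset parses matrices with separate label files or label columns", {
  dir <- withr::local_tempdir()
  m <- matrix(c(1.5, 2, 3, 4, 5, 6), 2, 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  mf <- file.path(dir, "m.tsv")
  utils::write.table(m, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  lf <- file.path(dir, "y.txt")
  writeLines(c("0", "1"), lf)
  ds <- readDataset(mf, labelsFile = lf)
  expect_equal(unname(ds$x), unname(m))
  expect_identical(ds$y, c(0L, 1L))
  # labels as a matrix column
  m2 <- cbind(m, label = c(1, 0))
  mf2 <- file.path(dir, "m2.tsv")
  utils::write.table(m2, mf2, sep = "\t", quote = FALSE, row.names = FALSE)
  ds2 <- readDataset(mf2, labelColumn = "label")
  expect_equal(ncol(ds2$x), 3)
  expect_identical(ds2$y, c(1L, 0L))
  # errors name the offending path / column
  expect_error(readDataset(file.path(dir, "absent.tsv"), labelsFile = lf),
               "absent.tsv")
  expect_error(readDataset(mf2, labelColumn = "nope"), "nope")
  expect_error(readDataset(mf), "labelsFile or labelColumn")
  writeLines(c("0", "2"), lf)
  expect_error(readDataset(mf, labelsFile = lf), "0,1")
})

test_that("runRank is reproducible and writes byte-identical score tables", {
  b <- syntheticBenchmark(n = 50, p = 40, g = 8, nRelevant = 2, seed = 101)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  t1 <- runRank(b@x, b@y, b@partition, trees = 50, seed = 7, outDir = d1)
  t2 <- runRank(b@x, b@y, b@partition, trees = 50, seed = 7, outDir = d2)
  expect_identical(t1@score, t2@score)
  expect_identical(groupRanking(t1), groupRanking(t2))
  expect_identical(readLines(file.path(d1, "scores.tsv")),
                   readLines(file.path(d2, "scores.tsv")))
  meta <- jsonlite::read_json(file.path(d1, "run.meta.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$seed, 7)
  expect_equal(meta$trees, 50)
  expect_equal(meta$groups, 8)
  # a different seed must change the forest (scores), not the invariants
  t3 <- runRank(b@x, b@y, b@partition, trees = 50, seed = 8)
  expect_false(identical(t1@score, t3@score))
  expect_setequal(t3@groupId, t1@groupId)
})

test_that("runBenchmark bookkeeping: rows per dataset, one mean row per cell, resumable", {
  grid <- data.frame(nRelevant = c(1L, 1L), n = c(40L, 40L),
                     k = c("sqrt", "1"), aggregation = c("avg", "sum"),
                     method = c("cer", "cer"), stringsAsFactors = FALSE)
  dir <- withr::local_tempdir()
  out <- runBenchmark(grid, nDatasets = 2, p = 30, g = 5, trees = 20,
                      nPerm = 4, seed = 11, outDir = dir)
  expect_equal(nrow(out$perDataset), 4)
  expect_equal(nrow(out$means), 2)
  expect_true(all(c("precision", "recall", "aupr", "rec1", "prec1") %in%
                    colnames(out$means)))
  expect_equal(out$means$precision[1],
               mean(out$perDataset$precision[out$perDataset$cell == 1]))
  expect_true(file.exists(file.path(dir, "results.tsv")))
  expect_true(file.exists(file.path(dir, "results_mean.tsv")))
  # per-dataset seeds depend only on (seed, cell, dataset): re-running a
  # single cell reproduces its rows exactly
  again <- runBenchmark(grid[1, , drop = FALSE], nDatasets = 2, p = 30,
                        g = 5, trees = 20, nPerm = 4, seed = 11)
  first <- out$perDataset[out$perDataset$cell == 1, ]
  rownames(first) <- rownames(again$perDataset) <- NULL
  expect_equal(again$perDataset, first)
})

test_that("the top-ranked group is a relevant group in most informative datasets", {
  hits <- 0L
  for (s in 1:10) {
    b <- syntheticBenchmark(n = 100, p = 100, g = 10, nRelevant = 3,
                            seed = 200 + s)
    tab <- runRank(b@x, b@y, b@partition, trees = 100, seed = 200 + s)
    hits <- hits + (groupRanking(tab)[1] %in% b@relevantGroups)
  }
  expect_gte(hits, 9L)
})

test_that("the command-line interface runs end to end on a small dataset", {
  cli <- system.file("scripts", "grouprf", package = "groupRF")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  dir <- withr::local_tempdir()
  withr::local_envvar(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))
  gen <- system2(rscript, c(cli, "generate", "--n", "30", "--p", "20",
                            "--g", "4", "--relevant", "1", "--seed", "5",
                            "--out-dir", dir),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "synthetic.matrix.tsv")))
  rankDir <- file.path(dir, "rank")
  system2(rscript, c(cli, "rank",
                     "--matrix", file.path(dir, "synthetic.matrix.tsv"),
                     "--labels", file.path(dir, "synthetic.labels.txt"),
                     "--partition", file.path(dir, "synthetic.partition.tsv"),
                     "--trees", "20", "--seed", "5", "--out-dir", rankDir),
          stdout = TRUE, stderr = TRUE)
  scores <- utils::read.delim(file.path(rankDir, "scores.tsv"))
  expect_equal(nrow(scores), 4)
  expect_true(all(c("group_id", "score", "rank") %in% colnames(scores)))
  selOut <- file.path(dir, "sel.tsv")
  system2(rscript, c(cli, "select",
                     "--matrix", file.path(dir, "synthetic.matrix.tsv"),
                     "--labels", file.path(dir, "synthetic.labels.txt"),
                     "--partition", file.path(dir, "synthetic.partition.tsv"),
                     "--method", "cer", "--permutations", "5",
                     "--trees", "20", "--seed", "5", "--out", selOut),
          stdout = TRUE, stderr = TRUE)
  sel <- utils::read.delim(selOut)
  expect_equal(nrow(sel), 4)
  expect_true(is.logical(sel$selected))
  metricsOut <- file.path(dir, "metrics.tsv")
  system2(rscript, c(cli, "evaluate", "--selection", selOut,
                     "--truth", file.path(dir, "synthetic.truth.json"),
                     "--out", metricsOut),
          stdout = TRUE, stderr = TRUE)
  metrics <- utils::read.delim(metricsOut)
  expect_equal(nrow(metrics), 1)
  expect_true(all(metrics$precision >= 0 & metrics$precision <= 1))
})
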