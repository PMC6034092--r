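# deterministic tiny instances: forests with bootstrap off and K = p are
# identical across RNG states, so permutation estimators can be compared
# exactly against exhaustive enumeration over all row permutations.

test_that("tail-group permutation shuffles exactly the tail columns with one shared vector", {
  set.seed(51)
  x <- matrix(rnorm(4 * 6), 4, 6)
  fp <- featurePartition(c("A", "A", "B", "C", "C", NA))
  ranking <- c("B", "A", "C")
  perm <- c(3L, 1L, 4L, 2L)
  xp <- permuteTailGroups(x, fp, ranking, i = 2, perm = perm)
  # row-shuffling oracle: tail groups A and C plus the unassigned feature
  tailCols <- c(1, 2, 4, 5, 6)
  expect_equal(xp[, tailCols], x[perm, tailCols])
  expect_equal(xp[, 3], x[, 3]) # head group B untouched
  # shared vector preserves within-tail correlation structure exactly
  expect_equal(cor(xp[, tailCols]), cor(x[, tailCols]))
  # identity permutation at i = 1 leaves the matrix unchanged
  expect_equal(permuteTailGroups(x, fp, ranking, 1, 1:4), x)
  # i = G permutes only the last-ranked group (and unassigned features)
  xg <- permuteTailGroups(x, fp, ranking, 3, perm)
  expect_equal(xg[, 1:3], x[, 1:3])
  expect_error(permuteTailGroups(x, fp, ranking, 4, perm), "1..G")
})

test_that("threshold selection rules follow first-crossing and max-rank semantics", {
  sc <- c(0.01, 0.02, 0.3, 0.04)
  expect_equal(unname(selectAtThreshold(sc, 0.05, "first_crossing")), 1:2)
  expect_equal(unname(selectAtThreshold(sc, 0.05, "max_rank")), 1:4)
  expect_length(selectAtThreshold(sc, 0), 0)
  expect_length(selectAtThreshold(sc, 0, "max_rank"), 0)
  # NA (unevaluated) ranks terminate the prefix
  expect_equal(unname(selectAtThreshold(c(0.01, NA, 0.01), 0.05)), 1L)
})

test_that("the eFDR false-positive count follows its order-statistic definition", {
  # observed ordered scores (5,4,3,2); at rank 2 permuted tail (4.5,1,0.5):
  # k = 1 holds (4.5 >= 4), k = 2 fails (1 < 3) -> V = 1
  expect_equal(groupRF:::.efdrV(c(4.5, 1, 0.5), c(4, 3, 2)), 1L)
  expect_equal(groupRF:::.efdrV(c(0, 0), c(1, 0.5)), 0L)   # all permuted zero
  expect_equal(groupRF:::.efdrV(c(9, 9), c(1, 0.5)), 2L)   # all dominate
  # cardinality bound V <= G - i + 1 by construction
  expect_lte(groupRF:::.efdrV(runif(5), runif(5)), 5L)
})

test_that("CER, CER^r and eFDR equal exhaustive permutation enumeration on a tiny instance", {
  x <- cbind(c(1, 2, 3, 4), c(2.5, 1.5, 4.5, 0.5), c(1.2, 3.4, 0.8, 2.9))
  y <- c(0L, 0L, 1L, 1L)
  fp <- featurePartition(c("gA", "gB", "gC"))
  perms <- allPermutations(4L)
  tab <- aggregateImportance(mdiImportance(detForest(x, y)), fp, "avg")
  res <- groupSelect(x, y, fp, methods = c("cer", "cerr", "efdr"),
                     table = tab, permutations = perms, trees = 1,
                     k = "all", bootstrap = FALSE, fullCurve = TRUE,
                     seed = 1)
  ranking <- groupRanking(tab)
  sObs <- tab@score
  G <- length(ranking)
  members <- groupMembers(fp)
  for (i in seq_len(G)) {
    cerHits <- 0; cerrHits <- 0; efdrSum <- 0
    for (perm in perms) {
      xp <- x
      for (g in ranking[i:G]) for (j in members[[g]]) xp[, j] <- x[perm, j]
      sp <- detGroupScores(xp, y, members, "avg") # named, partition order
      spr <- sp[ranking]
      if (max(spr[i:G]) >= sObs[i]) cerHits <- cerHits + 1
      pos <- match(ranking[i], names(sp)[order(-sp, seq_along(sp))])
      if (pos <= i) cerrHits <- cerrHits + 1
      srt <- sort(spr[i:G], decreasing = TRUE)
      V <- 0
      for (k in seq_len(G - i + 1)) {
        if (all(srt[seq_len(k)] >= sObs[i + seq_len(k) - 1])) V <- k
      }
      if (V > 0) efdrSum <- efdrSum + V / (V + i - 1)
    }
    P <- length(perms)
    expect_equal(statScores(res$cer)[[i]], cerHits / P, tolerance = 1e-15)
    expect_equal(statScores(res$cerr)[[i]], cerrHits / P, tolerance = 1e-15)
    expect_equal(statScores(res$efdr)[[i]], efdrSum / P, tolerance = 1e-15)
  }
})

test_that("mProbes equals exhaustive probe-permutation enumeration on a tiny instance", {
  x <- cbind(c(1, 2, 3), c(2, 3, 1))
  y <- c(0L, 1L, 1L)
  fp <- featurePartition(c("gA", "gB"))
  members <- groupMembers(fp)
  p3 <- allPermutations(3L)
  combos <- expand.grid(a = seq_along(p3), b = seq_along(p3))
  reps <- lapply(seq_len(nrow(combos)),
                 function(r) list(p3[[combos$a[r]]], p3[[combos$b[r]]]))
  tab <- aggregateImportance(mdiImportance(detForest(x, y)), fp, "avg")
  res <- mprobesSelect(x, y, fp, table = tab, permutations = reps,
                       trees = 1, k = "all", bootstrap = FALSE, seed = 1)
  fails <- c(gA = 0, gB = 0)
  for (r in reps) {
    xa <- cbind(x, x[r[[1]], 1], x[r[[2]], 2])
    imp <- oracleMDI(detForest(xa, y))
    real <- c(gA = imp[1], gB = imp[2])
    probeMax <- max(imp[3], imp[4])
    fails <- fails + (probeMax >= real)
  }
  oracle <- fails / length(reps)
  expect_equal(statScores(res), oracle[groupRanking(tab)],
               tolerance = 1e-15)
})

test_that("a zero observed score forces CER = 1 and constant groups are never selected", {
  x <- cbind(c(1, 2, 3, 4, 5, 6), rep(2, 6))
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  fp <- featurePartition(c("sep", "const"))
  tab <- aggregateImportance(mdiImportance(detForest(x, y)), fp, "avg")
  expect_equal(tab@score[tab@groupId == "const"], 0)
  res <- cerSelect(x, y, fp, table = tab, nPerm = 10, trees = 1, k = "all",
                   bootstrap = FALSE, fullCurve = TRUE, seed = 2)
  expect_equal(statScores(res)[["const"]], 1)
  expect_false("const" %in% selectedGroups(res))
})

test_that("CER^r on a single group is degenerate: score 1, nothing selected", {
  x <- cbind(c(1, 2, 3, 4), c(4, 3, 2, 1))
  y <- c(0L, 0L, 1L, 1L)
  fp <- featurePartition(c("only", "only"))
  res <- cerRankSelect(x, y, fp, nPerm = 5, trees = 1, k = "all",
                       bootstrap = FALSE, seed = 3)
  expect_equal(unname(statScores(res)), 1)
  expect_length(selectedGroups(res), 0)
})

test_that("statistical scores are 1/P-granular, bounded, and reproducible across joint and separate runs", {
  b <- syntheticBenchmark(n = 40, p = 30, g = 5, nRelevant = 2, seed = 71)
  P <- 7
  joint <- groupSelect(b@x, b@y, b@partition,
                       methods = c("cer", "cerr", "efdr", "mprobes"),
                       nPerm = P, trees = 30, seed = 9, fullCurve = TRUE)
  for (m in c("cer", "cerr", "mprobes")) {
    sc <- statScores(joint[[m]])
    sc <- sc[!is.na(sc)]
    expect_true(all(sc >= 0 & sc <= 1))
    expect_equal(sc * P, round(sc * P), tolerance = 1e-9) # multiples of 1/P
  }
  efdr <- statScores(joint$efdr)
  expect_true(all(efdr[!is.na(efdr)] >= 0 & efdr[!is.na(efdr)] <= 1))
  separate <- cerSelect(b@x, b@y, b@partition, nPerm = P, trees = 30,
                        seed = 9, fullCurve = TRUE)
  expect_identical(statScores(joint$cer), statScores(separate))
  again <- groupSelect(b@x, b@y, b@partition, methods = "mprobes",
                       nPerm = P, trees = 30, seed = 9)
  expect_identical(statScores(joint$mprobes), statScores(again))
})

test_that("early stopping halts evaluation at the first failing rank; full curves do not", {
  b <- syntheticBenchmark(n = 40, p = 30, g = 5, nRelevant = 1, seed = 81)
  stopped <- cerSelect(b@x, b@y, b@partition, nPerm = 5, trees = 20,
                       seed = 4)
  expect_lt(stopped@ranksEvaluated, nGroups(b@partition) + 1L)
  sc <- statScores(stopped)
  ev <- which(!is.na(sc))
  if (length(ev) < nGroups(b@partition)) {
    expect_gte(sc[max(ev)], stopped@alpha) # last evaluated rank crossed
    expect_true(all(sc[seq_len(max(ev) - 1)] < stopped@alpha))
  }
  full <- cerSelect(b@x, b@y, b@partition, nPerm = 5, trees = 20, seed = 4,
                    fullCurve = TRUE)
  expect_false(anyNA(statScores(full)))
  expect_equal(statScores(full)[ev], sc[ev])
})
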