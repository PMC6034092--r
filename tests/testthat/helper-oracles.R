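# Independent reference implementations used as oracles. They deliberately
# use naive explicit loops / enumeration, not the package's code paths.

# all n! permutations of 1..n, lexicographic
allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in allPermutations(n - 1L)) {
    for (pos in 0:(n - 1L)) out[[length(out) + 1L]] <- append(sub, n, pos)
  }
  lapply(out, as.integer)
}

giniOracle <- function(c0, c1) {
  m <- c0 + c1
  1 - (c0 / m)^2 - (c1 / m)^2
}

# exhaustive best-split CART (K = p, no bootstrap), flat preorder layout
# matching the fitted tree representation
oracleTreeFlat <- function(x, y) {
  env <- new.env()
  env$feature <- integer(); env$threshold <- numeric()
  env$left <- integer(); env$right <- integer()
  env$n <- integer(); env$c0 <- integer(); env$c1 <- integer()
  build <- function(idx) {
    c1 <- sum(y[idx] == 1); c0 <- length(idx) - c1; m <- length(idx)
    me <- length(env$feature) + 1L
    env$feature[me] <- NA_integer_; env$threshold[me] <- NA_real_
    env$left[me] <- NA_integer_; env$right[me] <- NA_integer_
    env$n[me] <- m; env$c0[me] <- c0; env$c1[me] <- c1
    if (c0 == 0L || c1 == 0L || m < 2L) return(me)
    g <- giniOracle(c0, c1)
    best <- list(delta = -1)
    for (f in seq_len(ncol(x))) {
      o <- order(x[idx, f]); vs <- x[idx, f][o]; ys <- y[idx][o]
      l0 <- 0L; l1 <- 0L
      for (t in seq_len(m - 1L)) {
        if (ys[t] == 0L) l0 <- l0 + 1L else l1 <- l1 + 1L
        if (vs[t + 1L] > vs[t]) {
          delta <- g - (t / m) * giniOracle(l0, l1) -
            ((m - t) / m) * giniOracle(c0 - l0, c1 - l1)
          if (delta > best$delta)
            best <- list(delta = delta, f = f, thr = (vs[t] + vs[t + 1L]) / 2)
        }
      }
    }
    if (best$delta < 0) return(me)
    env$feature[me] <- best$f; env$threshold[me] <- best$thr
    lidx <- idx[x[idx, best$f] <= best$thr]
    ridx <- idx[x[idx, best$f] > best$thr]
    env$left[me] <- build(lidx)
    env$right[me] <- build(ridx)
    me
  }
  build(seq_len(nrow(x)))
  list(feature = env$feature, threshold = env$threshold, left = env$left,
       right = env$right, n = env$n, c0 = env$c0, c1 = env$c1)
}

# node-walking MDI oracle: explicit loop over every interior node summing
# (n(N)/n) * DeltaI(N) from the stored node counts
oracleMDI <- function(forest) {
  out <- numeric(forest@nFeatures)
  for (tr in forest@trees) {
    nroot <- tr$n[1L]
    for (nd in seq_along(tr$feature)) {
      f <- tr$feature[nd]
      if (is.na(f)) next
      l <- tr$left[nd]; r <- tr$right[nd]
      delta <- giniOracle(tr$c0[nd], tr$c1[nd]) -
        (tr$n[l] / tr$n[nd]) * giniOracle(tr$c0[l], tr$c1[l]) -
        (tr$n[r] / tr$n[nd]) * giniOracle(tr$c0[r], tr$c1[r])
      out[f] <- out[f] + (tr$n[nd] / nroot) * delta
    }
  }
  out / length(forest@trees)
}

# per-tree leaf lookup + explicit vote count
oraclePredict <- function(forest, x) {
  n <- nrow(x)
  pred <- integer(n)
  for (i in seq_len(n)) {
    votes <- c(0L, 0L)
    for (tr in forest@trees) {
      nd <- 1L
      while (!is.na(tr$feature[nd])) {
        nd <- if (x[i, tr$feature[nd]] <= tr$threshold[nd]) tr$left[nd]
              else tr$right[nd]
      }
      cls <- if (tr$c1[nd] > tr$c0[nd]) 2L else 1L
      votes[cls] <- votes[cls] + 1L
    }
    pred[i] <- if (votes[2L] > votes[1L]) 1L else 0L
  }
  pred
}

# per-group aggregation by explicit per-feature looping
oracleAggregate <- function(importance, groupsOfFeatures, method) {
  vapply(groupsOfFeatures, function(cols) {
    vals <- numeric(0)
    for (j in cols) vals <- c(vals, importance[j])
    switch(method, sum = sum(vals), avg = mean(vals), max = max(vals))
  }, 0.0)
}

# prefix-walking AUPR oracle with trapezoid integration
oracleAUPR <- function(ranking, truth) {
  prec <- numeric(); rec <- numeric()
  for (k in seq_along(ranking)) {
    tp <- length(intersect(ranking[seq_len(k)], truth))
    prec[k] <- tp / k
    rec[k] <- tp / length(truth)
  }
  rec <- c(0, rec); prec <- c(prec[1], prec)
  a <- 0
  for (k in 2:length(rec))
    a <- a + (rec[k] - rec[k - 1]) * (prec[k] + prec[k - 1]) / 2
  a
}

# deterministic forest settings used by the enumeration oracles: no bootstrap,
# all features considered at each split -> identical trees, no RNG consumed
detForest <- function(x, y) groupForest(x, y, ntree = 1L, k = "all",
                                        bootstrap = FALSE)

detGroupScores <- function(x, y, members, method) {
  imp <- mdiImportance(detForest(x, y))
  oracleAggregate(imp, members, method)
}

# small labelled dataset separable by feature 1, used across forest tests
tinySeparable <- function() {
  x <- cbind(c(0.1, 0.4, 0.2, 0.3, 0.9, 0.7, 0.8, 0.6),
             c(0.5, 0.1, 0.9, 0.3, 0.2, 0.8, 0.4, 0.6))
  y <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  list(x = x, y = y)
}
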