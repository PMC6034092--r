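#' Gini impurity of a binary class distribution
#'
#' \code{1 - p0^2 - p1^2} where \code{p0}, \code{p1} are the class
#' proportions; ranges from 0 (pure node) to 0.5 (balanced node).
#'
#' @param counts non-negative integer vector of length 2 (class counts), not
#'   both zero.
#' @return impurity in [0, 0.5]
#' @examples
#' giniImpurity(c(5, 5)) # 0.5
#' giniImpurity(c(3, 1)) # 0.375
#' @export
giniImpurity <- function(counts) {
  stopifnot(length(counts) == 2, all(counts >= 0))
  if (sum(counts) == 0) stop("both class counts are zero")
  p <- counts / sum(counts)
  1 - p[1]^2 - p[2]^2
}

#' Resolve the number of candidate features per split
#'
#' @param k integer in 1..p, or \code{"sqrt"} (round(sqrt(p)), at least 1), or
#'   \code{"all"} (p).
#' @param p number of features
#' @return integer K
#' @export
resolveK <- function(k, p) {
  if (is.character(k)) {
    k <- match.arg(k, c("sqrt", "all"))
    k <- if (k == "sqrt") max(1L, as.integer(round(sqrt(p)))) else as.integer(p)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > p) stop("k must be in 1..p")
  k
}

#' Fit a Random Forests classifier
#'
#' Grows \code{ntree} fully developed CART trees (Gini criterion, no depth or
#' leaf-size limit) on a samples-by-features matrix with binary {0,1} labels.
#' Each tree is built on a bootstrap sample of size \code{n} (or on the
#' original sample when \code{bootstrap = FALSE}) and each split considers
#' \code{K} features drawn uniformly at random. All node statistics needed for
#' MDI importances are retained.
#'
#' Determinism: identical \code{(x, y, ntree, k, bootstrap, seed)} give
#' identical forests. With \code{bootstrap = FALSE} and \code{k = "all"} the
#' fit consumes no randomness and every tree is identical.
#'
#' @param x numeric matrix, samples in rows.
#' @param y labels, coercible to integers in {0, 1}; both classes required.
#' @param ntree number of trees T.
#' @param k candidate features per split; see [resolveK()].
#' @param bootstrap draw a bootstrap sample per tree.
#' @param seed optional integer seed (applied with \code{set.seed}).
#' @return a [GroupForest-class]
#' @export
groupForest <- function(x, y, ntree = 1000L, k = "sqrt", bootstrap = TRUE,
                        seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (nrow(x) < 2L) stop("need at least two samples")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (anyNA(y) || !all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (!all(is.finite(x))) stop("feature matrix contains non-finite values")
  if (ntree < 1L) stop("ntree must be >= 1")
  K <- resolveK(k, ncol(x))
  if (!is.null(seed)) set.seed(seed)
  trees <- .rf_fit(x, y, as.integer(ntree), K, isTRUE(bootstrap), TRUE)$trees
  new("GroupForest", trees = trees, nFeatures = ncol(x),
      nSamples = nrow(x),
      config = list(ntree = as.integer(ntree), k = K, bootstrap = bootstrap,
                    seed = seed))
}

setMethod("show", "GroupForest", function(object) {
  cat("GroupForest:", object@config$ntree, "trees,",
      object@nFeatures, "features,", object@nSamples, "samples, K =",
      object@config$k, if (object@config$bootstrap) "(bootstrap)" else
      "(no bootstrap)", "\n")
})

## internal fast path for the permutation procedures: fit and return only the
## MDI importance vector (accumulated during fitting, no tree materialization).
## Identical fits to groupForest() for the same RNG state; inputs are assumed
## pre-validated.
.fitImportance <- function(x, y, ntree, k, bootstrap) {
  .rf_fit(x, y, as.integer(ntree), resolveK(k, ncol(x)), isTRUE(bootstrap),
          FALSE)$importance
}

#' @describeIn mdiImportance MDI per Eq. I(x_i) = mean over trees of
#'   the sum over nodes splitting on x_i of (n(N)/n) * DeltaI(N), where
#'   DeltaI(N) = I(N) - n(N_l)/n(N) I(N_l) - n(N_r)/n(N) I(N_r) with Gini
#'   impurity I. Scores are NOT rescaled: their total equals the mean
#'   per-tree impurity reduction of the forest.
#' @export
setMethod("mdiImportance", "GroupForest", function(forest) {
  p <- forest@nFeatures
  total <- numeric(p)
  for (tr in forest@trees) {
    int <- which(!is.na(tr$feature))
    if (!length(int)) next
    n <- tr$n
    gini <- 1 - (tr$c0 / n)^2 - (tr$c1 / n)^2
    l <- tr$left[int]
    r <- tr$right[int]
    delta <- gini[int] - (n[l] / n[int]) * gini[l] - (n[r] / n[int]) * gini[r]
    contrib <- (n[int] / n[1L]) * delta
    agg <- rowsum(contrib, group = tr$feature[int], reorder = FALSE)
    total[as.integer(rownames(agg))] <- total[as.integer(rownames(agg))] +
      agg[, 1L]
  }
  total / length(forest@trees)
})

#' Predict class labels with a fitted forest
#'
#' Majority vote over the per-tree leaf predictions; vote ties (even T) go to
#' class 0.
#'
#' @param object a [GroupForest-class]
#' @param newdata numeric matrix with the same number of columns as the
#'   training matrix.
#' @param ... ignored
#' @return integer vector of 0/1 predictions
#' @export
setMethod("predict", "GroupForest", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object@nFeatures)
    stop("newdata has ", ncol(newdata), " columns, expected ",
         object@nFeatures)
  votes1 <- .rf_predict_votes(object@trees, newdata)
  as.integer(2L * votes1 > object@config$ntree)
})
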