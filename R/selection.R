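## Deterministic sub-seed per (protocol seed, rank, repetition) so that runs
## are reproducible and joint/separate/parallel evaluation of the methods give
## identical estimates. Kept below 2^31 - 1 for set.seed().
.deriveSeed <- function(seed, rank, rep) {
  as.integer((as.numeric(seed %% 1000003L) * 8191 +
              (rank + 1) * 97003 + rep * 262147) %% 2147483629)
}

#' Permute the features of the tail groups of a ranking
#'
#' Applies ONE row permutation identically to every feature belonging to the
#' groups ranked \code{i..G} (and to unassigned features), leaving features of
#' groups ranked \code{1..i-1} and the labels untouched. Using a single shared
#' permutation vector keeps the joint distribution of the permuted features
#' close to the original one while destroying their link to the labels.
#'
#' @param x samples-by-features matrix.
#' @param partition a [FeaturePartition-class].
#' @param ranking character vector of all group identifiers, best first.
#' @param i rank from which the tail starts (1 <= i <= G).
#' @param perm integer row permutation of \code{seq_len(nrow(x))}.
#' @return the permuted matrix
#' @export
permuteTailGroups <- function(x, partition, ranking, i, perm) {
  G <- length(ranking)
  if (i < 1 || i > G) stop("rank i must lie in 1..G")
  members <- groupMembers(partition)
  cols <- c(unlist(members[ranking[i:G]], use.names = FALSE),
            unassignedFeatures(partition))
  x[, cols] <- x[perm, cols]
  x
}

#' Select groups whose statistical score passes a risk threshold
#'
#' @param scores per-rank statistical scores, aligned to the ranking;
#'   \code{NA} marks ranks not evaluated (early stopping).
#' @param alpha risk level.
#' @param rule \code{"first_crossing"} (default): the longest prefix in which
#'   every score is below alpha; \code{"max_rank"}: all ranks up to the
#'   largest rank whose score is below alpha.
#' @return integer vector of selected ranks (named with the group identifiers
#'   when \code{scores} is named).
#' @export
selectAtThreshold <- function(scores, alpha,
                              rule = c("first_crossing", "max_rank")) {
  rule <- match.arg(rule)
  ok <- !is.na(scores) & scores < alpha
  if (rule == "first_crossing") {
    bad <- which(!ok)
    r <- if (length(bad)) bad[1L] - 1L else length(scores)
  } else {
    r <- if (any(ok)) max(which(ok)) else 0L
  }
  sel <- seq_len(r)
  if (!is.null(names(scores))) names(sel) <- names(scores)[sel]
  sel
}

## False-positive count V_i at rank i: with the permuted tail scores ordered
## descending (s^p_(1) >= s^p_(2) >= ...), V_i is the largest k such that
## s^p_(j) >= s_obs[i+j-1] for every j <= k (0 when already the first
## comparison fails). sObsTail is the observed score vector at ranks i..G.
.efdrV <- function(permTail, sObsTail) {
  holds <- unname(sort(permTail, decreasing = TRUE) >= sObsTail)
  if (!holds[1L]) return(0L)
  w <- which(!holds)
  if (length(w)) w[1L] - 1L else length(holds)
}

## Shared engine for the tail-permutation methods (CER, CER^r, eFDR).
## Returns a G x length(methods) matrix of statistical scores, NA at ranks a
## method did not evaluate. Per repetition one forest is refitted on the
## tail-permuted matrix; the three statistics are read off the same refit, so
## running them jointly or separately gives identical estimates.
.permutationCurves <- function(x, y, partition, table, methods, nPerm, alpha,
                               trees, k, bootstrap, seed, fullCurve,
                               permutations, verbose) {
  ranking <- table@groupId
  sObs <- table@score
  G <- length(ranking)
  n <- nrow(x)
  agg <- table@aggregation
  members <- groupMembers(partition)
  gOrder <- groupIds(partition)
  rankIdx <- match(ranking, gOrder)
  unass <- unassignedFeatures(partition)
  P <- if (is.null(permutations)) as.integer(nPerm) else length(permutations)

  curves <- matrix(NA_real_, nrow = G, ncol = length(methods),
                   dimnames = list(NULL, methods))
  active <- methods
  for (i in seq_len(G)) {
    if (!length(active)) break
    if (verbose) message("rank ", i, "/", G, " (", P, " refits)")
    tailCols <- c(unlist(members[rankIdx[i:G]], use.names = FALSE), unass)
    cerHits <- 0L; cerrHits <- 0L; efdrSum <- 0
    for (rep in seq_len(P)) {
      set.seed(.deriveSeed(seed, i, rep))
      perm <- if (is.null(permutations)) sample.int(n) else permutations[[rep]]
      xp <- x
      xp[, tailCols] <- x[perm, tailCols]
      imp <- .fitImportance(xp, y, trees, k, bootstrap)
      sp <- .aggScores(imp, members, agg)
      spr <- sp[rankIdx]
      if ("cer" %in% active && max(spr[i:G]) >= sObs[i])
        cerHits <- cerHits + 1L
      if ("cerr" %in% active) {
        names(sp) <- gOrder
        if (match(ranking[i], rankGroups(sp)) <= i) cerrHits <- cerrHits + 1L
      }
      if ("efdr" %in% active) {
        V <- .efdrV(spr[i:G], sObs[i:G])
        if (V > 0L) efdrSum <- efdrSum + V / (V + i - 1)
      }
    }
    est <- c(cer = cerHits / P, cerr = cerrHits / P, efdr = efdrSum / P)
    for (m in active) curves[i, m] <- est[[m]]
    if (!fullCurve) active <- active[curves[i, active] < alpha]
  }
  curves
}

## mProbes: per repetition augment the matrix with one shuffled probe copy of
## every group (each probe gets its own single row-permutation vector, shared
## by the features inside that probe), refit one forest on the 2p'-feature
## matrix, and count for each original group whether any probe group scores at
## least as high in that run. Returns per-rank scores aligned to the table.
.mprobesCurve <- function(x, y, partition, table, nPerm, trees, k, bootstrap,
                          seed, permutations, verbose) {
  members <- groupMembers(partition)
  gOrder <- groupIds(partition)
  G <- length(gOrder)
  n <- nrow(x)
  agg <- table@aggregation
  sizes <- lengths(members)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  probeMembers <- lapply(seq_len(G),
                         function(j) ncol(x) + (starts[j]:ends[j]))
  P <- if (is.null(permutations)) as.integer(nPerm) else length(permutations)
  fails <- numeric(G)
  for (rep in seq_len(P)) {
    if (verbose && rep %% 50L == 0L) message("mProbes repetition ", rep, "/", P)
    set.seed(.deriveSeed(seed, 0L, rep))
    perms <- if (is.null(permutations))
      replicate(G, sample.int(n), simplify = FALSE)
    else permutations[[rep]]
    probeBlock <- matrix(0, n, sum(sizes))
    for (j in seq_len(G))
      probeBlock[, starts[j]:ends[j]] <- x[perms[[j]], members[[j]],
                                           drop = FALSE]
    imp <- .fitImportance(cbind(x, probeBlock), y, trees, k, bootstrap)
    real <- .aggScores(imp, members, agg)
    probeMax <- max(.aggScores(imp, probeMembers, agg))
    fails <- fails + (probeMax >= real)
  }
  scores <- fails / P
  scores[match(table@groupId, gOrder)]
}

#' Permutation-based statistical scoring and selection of feature groups
#'
#' Turns a group-importance ranking into statistical scores with one or more
#' of four procedures, then selects groups at risk level \code{alpha}:
#' \describe{
#'   \item{cer}{Conditional error rate, an FWER estimate: the fraction of
#'     permutation repetitions in which, with groups ranked \code{i..G}
#'     rendered irrelevant by a shared row permutation and the forest
#'     refitted, the best permuted tail-group score reaches the observed
#'     score at rank \code{i}.}
#'   \item{cerr}{Rank-based CER variant: the fraction of repetitions in which
#'     the group observed at rank \code{i} still attains rank \code{<= i}
#'     among all permuted-data group scores.}
#'   \item{efdr}{Permutation FDR estimate: the mean over repetitions of
#'     \code{V_i / (V_i + i - 1)} where \code{V_i} is the largest \code{k}
#'     such that the k largest permuted tail scores dominate the observed
#'     scores at ranks \code{i..i+k-1} element-wise (0/0 is defined as 0).}
#'   \item{mprobes}{Random-probes FWER estimate: the fraction of repetitions
#'     in which, after augmenting the data with a shuffled probe copy of
#'     every group and refitting, any probe group scores at least as high as
#'     the group.}
#' }
#' The tail-permutation methods share one permutation scheme: per repetition a
#' single row permutation is applied to all features of the tail groups (and
#' to unassigned features). All three are read off the same refits when
#' requested together. Evaluation of cer/cerr/efdr proceeds from rank 1 and,
#' unless \code{fullCurve = TRUE}, stops after the first rank whose score
#' reaches \code{alpha} (their cost is G x P forest refits otherwise).
#' Domination comparisons use \code{>=}: a tie counts against the real group.
#'
#' @param x samples-by-features numeric matrix.
#' @param y binary {0,1} labels.
#' @param partition a [FeaturePartition-class].
#' @param methods subset of \code{c("cer", "cerr", "efdr", "mprobes")}.
#' @param aggregation group aggregation function (used when \code{table} is
#'   not supplied and for all permuted refits).
#' @param nPerm number of permutation repetitions P.
#' @param alpha risk level in (0, 1).
#' @param trees,k,bootstrap forest parameters per refit; see [groupForest()].
#'   Symbolic \code{k} ("sqrt"/"all") is resolved against the width of the
#'   matrix actually fitted (so mProbes resolves it on the augmented matrix).
#' @param seed integer seed driving the whole procedure; repetition sub-seeds
#'   derive deterministically from (seed, rank, repetition).
#' @param rule selection rule, see [selectAtThreshold()].
#' @param fullCurve evaluate every rank (no early stopping), e.g. for
#'   score-vs-rank curves.
#' @param table optional precomputed observed [GroupScoreTable-class]; when
#'   missing it is computed from a forest fitted with the same parameters and
#'   \code{seed}.
#' @param permutations optional explicit permutations overriding the random
#'   draws (then \code{nPerm} is their count): for cer/cerr/efdr a list of row
#'   permutation vectors, one per repetition; for mprobes a list of
#'   repetitions, each a list with one permutation per group. Used for
#'   exhaustive-enumeration checks.
#' @param verbose report per-rank progress.
#' @return a [SelectionResult-class], or a named list of them when several
#'   methods are requested.
#' @references stats are multiples of 1/P; P must exceed 1/alpha for any
#'   selection to be possible.
#' @export
groupSelect <- function(x, y, partition, methods = "cer",
                        aggregation = c("avg", "sum", "max"),
                        nPerm = 1000L, alpha = 0.05,
                        trees = 1000L, k = "sqrt", bootstrap = TRUE,
                        seed = 1L, rule = c("first_crossing", "max_rank"),
                        fullCurve = FALSE, table = NULL, permutations = NULL,
                        verbose = FALSE) {
  methods <- match.arg(methods, c("cer", "cerr", "efdr", "mprobes"),
                       several.ok = TRUE)
  aggregation <- match.arg(aggregation)
  rule <- match.arg(rule)
  stopifnot(alpha > 0, alpha < 1, nPerm >= 1)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (is.null(table)) {
    forest <- groupForest(x, y, ntree = trees, k = k, bootstrap = bootstrap,
                          seed = seed)
    table <- aggregateImportance(mdiImportance(forest), partition,
                                 aggregation)
  } else {
    stopifnot(is(table, "GroupScoreTable"))
    aggregation <- table@aggregation
  }
  protocol <- list(seed = seed, nPerm = nPerm, alpha = alpha, trees = trees,
                   k = k, bootstrap = bootstrap, aggregation = aggregation,
                   rule = rule)
  out <- list()
  permMethods <- intersect(methods, c("cer", "cerr", "efdr"))
  if (length(permMethods)) {
    curves <- .permutationCurves(x, y, partition, table, permMethods, nPerm,
                                 alpha, trees, k, bootstrap, seed, fullCurve,
                                 permutations, verbose)
    for (m in permMethods) {
      sc <- curves[, m]
      names(sc) <- table@groupId
      sel <- selectAtThreshold(sc, alpha, rule)
      out[[m]] <- new("SelectionResult", method = m, table = table,
                      statScore = unname(sc), selected = table@groupId[sel],
                      alpha = alpha, rule = rule,
                      ranksEvaluated = as.integer(sum(!is.na(sc))),
                      protocol = protocol)
    }
  }
  if ("mprobes" %in% methods) {
    sc <- .mprobesCurve(x, y, partition, table, nPerm, trees, k, bootstrap,
                        seed, permutations, verbose)
    names(sc) <- table@groupId
    sel <- selectAtThreshold(sc, alpha, rule)
    out[["mprobes"]] <- new("SelectionResult", method = "mprobes",
                            table = table, statScore = unname(sc),
                            selected = table@groupId[sel], alpha = alpha,
                            rule = rule,
                            ranksEvaluated = length(sc),
                            protocol = protocol)
  }
  if (length(methods) == 1L) out[[methods]] else out[methods]
}

#' @rdname groupSelect
#' @param ... passed on to [groupSelect()]
#' @export
cerSelect <- function(x, y, partition, ...)
  groupSelect(x, y, partition, methods = "cer", ...)

#' @rdname groupSelect
#' @export
cerRankSelect <- function(x, y, partition, ...)
  groupSelect(x, y, partition, methods = "cerr", ...)

#' @rdname groupSelect
#' @export
efdrSelect <- function(x, y, partition, ...)
  groupSelect(x, y, partition, methods = "efdr", ...)

#' @rdname groupSelect
#' @export
mprobesSelect <- function(x, y, partition, ...)
  groupSelect(x, y, partition, methods = "mprobes", ...)

#' @describeIn SelectionResult-class selected group identifiers
#' @param object,x a \code{SelectionResult}
#' @export
setMethod("selectedGroups", "SelectionResult", function(object)
  object@selected)

#' @describeIn SelectionResult-class per-rank statistical scores, named by
#'   group identifier
#' @export
setMethod("statScores", "SelectionResult", function(object) {
  sc <- object@statScore
  names(sc) <- object@table@groupId
  sc
})

#' @describeIn SelectionResult-class coerce to a per-rank data.frame with
#'   columns \code{rank}, \code{group_id}, \code{observed_score},
#'   \code{stat_score}, \code{method}, \code{selected}
#' @export
setMethod("as.data.frame", "SelectionResult", function(x, ...) {
  data.frame(rank = x@table@rank, group_id = x@table@groupId,
             observed_score = x@table@score, stat_score = x@statScore,
             method = x@method,
             selected = x@table@groupId %in% x@selected,
             stringsAsFactors = FALSE)
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult [", object@method, "], alpha = ", object@alpha,
      ", rule = ", object@rule, "\n", sep = "")
  cat("selected ", length(object@selected), " group(s): ",
      paste(object@selected, collapse = ", "), "\n", sep = "")
  cat("ranks evaluated:", object@ranksEvaluated, "of",
      length(object@statScore), "\n")
})

#' Write a selection result and its run metadata
#'
#' Writes the per-rank table (tab-separated) and a \code{<file>.meta.json}
#' sidecar holding the full protocol (seed, P, alpha, forest parameters,
#' aggregation, rule) needed to reproduce the run.
#'
#' @param result a [SelectionResult-class]
#' @param file output path for the table
#' @export
writeSelection <- function(result, file) {
  utils::write.table(as.data.frame(result), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(c(result@protocol, list(method = result@method)),
                       paste0(file, ".meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(file)
}
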