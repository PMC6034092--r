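#' @import methods
NULL

#' Disjoint assignment of features to named groups
#'
#' A \code{FeaturePartition} maps each of \code{p} features to at most one
#' named group (brain region, gene set, ...). Features without a group are
#' "unassigned": they still take part in forest fitting but contribute to no
#' group score.
#'
#' @slot groupIds ordered character vector of group identifiers; the order is
#'   the identifier order used for tie-breaking in rankings.
#' @slot assignment integer vector of length \code{p}; \code{assignment[i]} is
#'   the index into \code{groupIds} of the group of feature \code{i}, or
#'   \code{NA} for unassigned features.
#' @slot featureIds character vector of length \code{p} naming the features.
#' @slot metadata list of provenance information (e.g. the voxel linearization
#'   order for atlas-derived partitions).
#'
#' @seealso [featurePartition()], [partitionFromAtlas()], [readPartitionTable()]
#' @export
setClass("FeaturePartition",
  representation(
    groupIds = "character",
    assignment = "integer",
    featureIds = "character",
    metadata = "list"
  )
)

setValidity("FeaturePartition", function(object) {
  msg <- character()
  g <- object@groupIds
  a <- object@assignment
  if (anyDuplicated(g)) msg <- c(msg, "group identifiers must be unique")
  if (any(!nzchar(g))) msg <- c(msg, "group identifiers must be non-empty")
  if (length(a) != length(object@featureIds))
    msg <- c(msg, "assignment and featureIds lengths differ")
  if (anyDuplicated(object@featureIds))
    msg <- c(msg, "feature identifiers must be unique")
  used <- a[!is.na(a)]
  if (length(used) && (min(used) < 1L || max(used) > length(g)))
    msg <- c(msg, "assignment indexes outside groupIds")
  if (length(g) && !all(seq_along(g) %in% used))
    msg <- c(msg, "every listed group must contain at least one feature")
  if (length(msg)) msg else TRUE
})

#' Fitted Random Forests classifier with full node bookkeeping
#'
#' Stores every tree with, at each node, the split feature, threshold, the
#' number of training examples reaching the node and the per-class counts, as
#' needed to compute Mean Decrease of Impurity importances.
#'
#' @slot trees list of trees; each tree is a list of parallel node vectors
#'   (\code{feature}, \code{threshold}, \code{left}, \code{right}, \code{n},
#'   \code{c0}, \code{c1}) with \code{NA} feature marking leaves.
#' @slot nFeatures,nSamples dimensions of the training matrix.
#' @slot config list with the resolved fitting parameters
#'   (\code{ntree}, \code{k}, \code{bootstrap}, \code{seed}).
#'
#' @seealso [groupForest()], [mdiImportance()]
#' @export
setClass("GroupForest",
  representation(
    trees = "list",
    nFeatures = "integer",
    nSamples = "integer",
    config = "list"
  )
)

#' Per-group aggregated importance scores
#'
#' Rows are ordered by rank (rank 1 = highest score). Scores are aggregated
#' per-feature MDI importances: the sum, average or max over the features of
#' each group.
#'
#' @slot groupId character, group identifiers in rank order.
#' @slot size integer, number of features per group.
#' @slot score numeric, aggregated importance (non-increasing along ranks).
#' @slot rank integer, 1..G.
#' @slot aggregation one of \code{"sum"}, \code{"avg"}, \code{"max"}.
#'
#' @seealso [aggregateImportance()]
#' @export
setClass("GroupScoreTable",
  representation(
    groupId = "character",
    size = "integer",
    score = "numeric",
    rank = "integer",
    aggregation = "character"
  )
)

setValidity("GroupScoreTable", function(object) {
  msg <- character()
  G <- length(object@groupId)
  if (length(object@score) != G || length(object@rank) != G ||
      length(object@size) != G)
    msg <- c(msg, "all columns must have one entry per group")
  if (G && !identical(sort(object@rank), seq_len(G)))
    msg <- c(msg, "ranks must be a permutation of 1..G")
  if (G && is.unsorted(-object@score))
    msg <- c(msg, "scores must be non-increasing along ranks")
  if (any(object@score < 0)) msg <- c(msg, "scores must be non-negative")
  if (!object@aggregation %in% c("sum", "avg", "max"))
    msg <- c(msg, "aggregation must be sum, avg or max")
  if (length(msg)) msg else TRUE
})

#' Result of a permutation-based group selection procedure
#'
#' Holds, per rank of the observed group ranking, the statistical score
#' (an estimated FWER or FDR in [0, 1]) of one of the methods CER, CER^r,
#' eFDR or mProbes, plus the groups selected at level alpha.
#'
#' @slot method one of \code{"cer"}, \code{"cerr"}, \code{"efdr"},
#'   \code{"mprobes"}.
#' @slot table the observed [GroupScoreTable-class] the procedure scored.
#' @slot statScore numeric per rank; \code{NA} for ranks not evaluated under
#'   sequential early stopping.
#' @slot selected character, selected group identifiers (a prefix of the
#'   ranking under the default rule).
#' @slot alpha risk level.
#' @slot rule \code{"first_crossing"} or \code{"max_rank"}.
#' @slot ranksEvaluated number of ranks whose score was estimated.
#' @slot protocol list of run parameters (seed, nPerm, trees, k, ...).
#'
#' @seealso [groupSelect()], [selectAtThreshold()]
#' @export
setClass("SelectionResult",
  representation(
    method = "character",
    table = "GroupScoreTable",
    statScore = "numeric",
    selected = "character",
    alpha = "numeric",
    rule = "character",
    ranksEvaluated = "integer",
    protocol = "list"
  )
)

setValidity("SelectionResult", function(object) {
  msg <- character()
  s <- object@statScore
  if (length(s) != length(object@table@groupId))
    msg <- c(msg, "one statistical score per rank required")
  ok <- s[!is.na(s)]
  if (length(ok) && (any(ok < 0) || any(ok > 1)))
    msg <- c(msg, "statistical scores must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic linear group-structured classification benchmark
#'
#' A generated dataset together with its ground truth: which groups are
#' relevant, the latent drivers, the linear weights and which labels were
#' flipped.
#'
#' @slot x numeric matrix, samples by features.
#' @slot y integer labels in {0, 1}.
#' @slot partition the known [FeaturePartition-class].
#' @slot relevantGroups identifiers of the truly relevant groups.
#' @slot weights linear combination weights, one per relevant group.
#' @slot latents matrix of latent drivers (n by R).
#' @slot flipped indices of label-flipped samples.
#' @slot spec list of generator parameters (n, p, g, nRelevant,
#'   flipFraction, seed).
#'
#' @seealso [syntheticBenchmark()]
#' @export
setClass("SyntheticBenchmark",
  representation(
    x = "matrix",
    y = "integer",
    partition = "FeaturePartition",
    relevantGroups = "character",
    weights = "numeric",
    latents = "matrix",
    flipped = "integer",
    spec = "list"
  )
)
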