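## internal: per-group aggregated scores as a bare numeric vector, in the
## partition's group order. Hot path of the permutation procedures.
.aggScores <- function(importance, members, method) {
  switch(method,
    sum = vapply(members, function(ix) sum(importance[ix]), 0.0),
    avg = vapply(members, function(ix) sum(importance[ix]) / length(ix), 0.0),
    max = vapply(members, function(ix) max(importance[ix]), 0.0),
    stop("unknown aggregation method: ", method)
  )
}

#' Rank groups by descending score
#'
#' Stable descending sort; ties are broken by the order in which the group
#' identifiers are listed, so rankings are reproducible.
#'
#' @param scores named numeric vector of per-group scores.
#' @return character vector of group identifiers, best first.
#' @examples
#' rankGroups(c(A = 0.2, B = 0.5)) # "B" "A"
#' @export
rankGroups <- function(scores) {
  stopifnot(!is.null(names(scores)))
  names(scores)[order(-scores, seq_along(scores))]
}

#' Aggregate per-feature importances into group importances
#'
#' Computes, for every group G with features x_1..x_#G,
#' \code{I_sum = sum_j I(x_j)}, \code{I_avg = I_sum / #G} or
#' \code{I_max = max_j I(x_j)}, then ranks groups by descending score.
#' Unassigned features are ignored.
#'
#' @param importance numeric vector of per-feature MDI scores (see
#'   [mdiImportance()]); its length must equal the partition's feature count.
#' @param partition a [FeaturePartition-class].
#' @param method aggregation function: \code{"sum"}, \code{"avg"} or
#'   \code{"max"}.
#' @return a [GroupScoreTable-class], rows in rank order.
#' @export
aggregateImportance <- function(importance, partition,
                                method = c("sum", "avg", "max")) {
  method <- match.arg(method)
  if (length(importance) != nFeatures(partition))
    stop("importance length (", length(importance),
         ") does not match partition feature count (",
         nFeatures(partition), ")")
  members <- groupMembers(partition)
  scores <- .aggScores(importance, members, method)
  names(scores) <- groupIds(partition)
  ord <- order(-scores, seq_along(scores))
  sizes <- groupSizes(partition)
  new("GroupScoreTable",
      groupId = names(scores)[ord],
      size = as.integer(sizes[ord]),
      score = as.numeric(scores[ord]),
      rank = seq_along(ord),
      aggregation = method)
}

#' @describeIn GroupScoreTable-class group identifiers in rank order
#' @param object,x a \code{GroupScoreTable}
#' @export
setMethod("groupRanking", "GroupScoreTable", function(object) object@groupId)

#' @describeIn GroupScoreTable-class coerce to a data.frame with columns
#'   \code{group_id}, \code{size}, \code{score}, \code{rank},
#'   \code{aggregation}
#' @export
setMethod("as.data.frame", "GroupScoreTable", function(x, ...) {
  data.frame(group_id = x@groupId, size = x@size, score = x@score,
             rank = x@rank, aggregation = x@aggregation,
             stringsAsFactors = FALSE)
})

setMethod("show", "GroupScoreTable", function(object) {
  cat("GroupScoreTable (", object@aggregation, " aggregation, ",
      length(object@groupId), " groups)\n", sep = "")
  print(utils::head(as.data.frame(object), 10))
  if (length(object@groupId) > 10) cat("...\n")
})

#' Write a group score table
#'
#' Tab-separated columns \code{group_id  size  score  rank  aggregation}.
#'
#' @param table a [GroupScoreTable-class]
#' @param file output path
#' @export
writeGroupScores <- function(table, file) {
  utils::write.table(as.data.frame(table), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
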