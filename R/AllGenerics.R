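#' @rdname FeaturePartition-class
#' @param object,x a \code{FeaturePartition}
#' @export
setGeneric("groupIds", function(object) standardGeneric("groupIds"))

#' @rdname FeaturePartition-class
#' @export
setGeneric("groupSizes", function(object) standardGeneric("groupSizes"))

#' @rdname FeaturePartition-class
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))

#' @rdname FeaturePartition-class
#' @export
setGeneric("nGroups", function(object) standardGeneric("nGroups"))

#' @rdname FeaturePartition-class
#' @export
setGeneric("groupMembers", function(object) standardGeneric("groupMembers"))

#' Per-feature Mean Decrease of Impurity importances
#'
#' @param forest a [GroupForest-class]
#' @return numeric vector of unnormalized MDI scores, one per feature
#' @export
setGeneric("mdiImportance", function(forest) standardGeneric("mdiImportance"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectedGroups", function(object) standardGeneric("selectedGroups"))

#' @rdname SelectionResult-class
#' @export
setGeneric("statScores", function(object) standardGeneric("statScores"))

#' @rdname GroupScoreTable-class
#' @export
setGeneric("groupRanking", function(object) standardGeneric("groupRanking"))
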