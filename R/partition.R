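#' Construct a feature partition
#'
#' @param groups character vector of length \code{p}: the group identifier of
#'   each feature, \code{NA} for unassigned features. Group order is
#'   first-appearance order unless \code{groupOrder} is given.
#' @param featureIds optional character vector of feature names; defaults to
#'   \code{"0" ... "p-1"} (zero-based indices, matching the table format).
#' @param groupOrder optional explicit ordering of the group identifiers.
#' @param metadata optional provenance list.
#' @return a [FeaturePartition-class]
#' @examples
#' fp <- featurePartition(c("A", "A", "B", NA))
#' groupSizes(fp)
#' @export
featurePartition <- function(groups, featureIds = NULL, groupOrder = NULL,
                             metadata = list()) {
  groups <- as.character(groups)
  p <- length(groups)
  if (is.null(featureIds)) featureIds <- as.character(seq_len(p) - 1L)
  ids <- if (is.null(groupOrder)) unique(groups[!is.na(groups)]) else groupOrder
  assignment <- match(groups, ids)
  if (any(!is.na(groups) & is.na(assignment)))
    stop("groups contain identifiers absent from groupOrder")
  new("FeaturePartition", groupIds = as.character(ids),
      assignment = as.integer(assignment),
      featureIds = as.character(featureIds), metadata = metadata)
}

#' @rdname FeaturePartition-class
#' @export
setMethod("groupIds", "FeaturePartition", function(object) object@groupIds)

#' @rdname FeaturePartition-class
#' @export
setMethod("groupSizes", "FeaturePartition", function(object) {
  sz <- tabulate(object@assignment, nbins = length(object@groupIds))
  names(sz) <- object@groupIds
  sz
})

#' @rdname FeaturePartition-class
#' @export
setMethod("nFeatures", "FeaturePartition",
          function(object) length(object@assignment))

#' @rdname FeaturePartition-class
#' @export
setMethod("nGroups", "FeaturePartition",
          function(object) length(object@groupIds))

#' @describeIn FeaturePartition-class list of per-group feature index vectors
#'   (1-based column indices), named by group identifier.
#' @export
setMethod("groupMembers", "FeaturePartition", function(object) {
  members <- split(seq_along(object@assignment), object@assignment)
  out <- rep(list(integer()), length(object@groupIds))
  names(out) <- object@groupIds
  out[as.integer(names(members))] <- members
  names(out) <- object@groupIds
  out
})

#' @describeIn FeaturePartition-class indices of features assigned to no group
#' @export
unassignedFeatures <- function(object) {
  stopifnot(is(object, "FeaturePartition"))
  which(is.na(object@assignment))
}

setMethod("show", "FeaturePartition", function(object) {
  sz <- groupSizes(object)
  cat("FeaturePartition:", length(object@assignment), "features,",
      length(object@groupIds), "groups,",
      sum(is.na(object@assignment)), "unassigned\n")
  cat("group sizes: min", if (length(sz)) min(sz) else NA,
      "median", if (length(sz)) stats::median(sz) else NA,
      "max", if (length(sz)) max(sz) else NA, "\n")
})

#' @describeIn FeaturePartition-class coerce to a two-column data.frame
#'   (assigned features only)
#' @export
setMethod("as.data.frame", "FeaturePartition", function(x, ...) {
  keep <- !is.na(x@assignment)
  data.frame(feature_id = x@featureIds[keep],
             group_id = x@groupIds[x@assignment[keep]],
             stringsAsFactors = FALSE)
})

#' Read a feature-to-group partition table
#'
#' The table format is tab-separated with a header line and two columns,
#' \code{feature_id} and \code{group_id}. Feature ids are zero-based integer
#' indices into the feature space. Features absent from the table are
#' unassigned. Group order is first-appearance order.
#'
#' @param file path to the table.
#' @param expectedFeatureCount total number of features \code{p} (>= 1).
#' @return a [FeaturePartition-class]
#' @export
readPartitionTable <- function(file, expectedFeatureCount) {
  stopifnot(expectedFeatureCount >= 1)
  tab <- utils::read.delim(file, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2)
    stop("partition table must have columns feature_id and group_id")
  fid <- suppressWarnings(as.integer(tab[[1]]))
  if (anyNA(fid)) stop("feature ids must be integers")
  if (anyDuplicated(fid)) stop("duplicate feature id in partition table")
  if (any(fid < 0L | fid >= expectedFeatureCount))
    stop("feature id outside [0, expectedFeatureCount)")
  groups <- rep(NA_character_, expectedFeatureCount)
  groups[fid + 1L] <- tab[[2]]
  featurePartition(groups, metadata = list(source = file))
}

#' Write a partition table
#'
#' Writes the assigned features as a two-column tab-separated file
#' \code{feature_id<TAB>group_id} with a header line; the inverse of
#' [readPartitionTable()].
#'
#' @param partition a [FeaturePartition-class]
#' @param file output path
#' @export
writePartitionTable <- function(partition, file) {
  utils::write.table(as.data.frame(partition), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Build a feature partition from a NIfTI atlas and brain mask
#'
#' Features are the in-mask voxels, linearized in R array order (first axis
#' fastest, i.e. column-major); this order defines feature identity and is
#' recorded in the partition metadata. Each in-mask voxel with atlas label
#' \code{L > 0} is assigned to group \code{"L"}; label-0 (background) voxels
#' are unassigned unless \code{poolBackground = TRUE}, in which case they form
#' a single group \code{"background"}. Groups are ordered by ascending label.
#'
#' @param atlas 3-D integer label array, or path to a NIfTI volume.
#' @param mask 3-D binary array of the same dimensions, or a NIfTI path.
#' @param poolBackground pool in-mask label-0 voxels into a "background"
#'   group instead of leaving them unassigned.
#' @return a [FeaturePartition-class] whose features are the in-mask voxels.
#' @export
partitionFromAtlas <- function(atlas, mask, poolBackground = FALSE) {
  if (is.character(atlas)) atlas <- as.array(RNifti::readNifti(atlas))
  if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask))
  atlas <- as.array(atlas); mask <- as.array(mask)
  if (!identical(dim(atlas), dim(mask)))
    stop("atlas and mask dimensions differ")
  if (any(atlas < 0) || any(atlas != round(atlas)))
    stop("atlas labels must be non-negative integers")
  inMask <- which(mask != 0)           # R array order: first axis fastest
  if (!length(inMask)) stop("mask is empty")
  labels <- as.integer(round(atlas[inMask]))
  groups <- ifelse(labels > 0L, as.character(labels),
                   if (poolBackground) "background" else NA_character_)
  present <- sort(unique(labels[labels > 0L]))
  ord <- as.character(present)
  if (poolBackground && any(labels == 0L)) ord <- c(ord, "background")
  featurePartition(groups,
                   featureIds = as.character(inMask - 1L),
                   groupOrder = ord,
                   metadata = list(linearization = "column-major (first axis fastest)",
                                   volumeDim = dim(atlas),
                                   nInMask = length(inMask)))
}
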