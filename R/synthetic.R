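#' Draw random contiguous group sizes
#'
#' Draws \code{g - 1} distinct cut-off values uniformly without replacement
#' from \code{{1, ..., p-1}}; with \code{c_0 = 0} and \code{c_g = p}, size i is
#' \code{c_i - c_{i-1}}. All sizes are >= 1 and sum to p. (Cut-offs are drawn
#' from \code{1..p-1}, not \code{1..p}, since a cut-off at p would create an
#' empty final group.) Uses the current RNG state.
#'
#' @param p number of features
#' @param g number of groups (g <= p)
#' @return integer vector of g group sizes
#' @export
samplePartitionSizes <- function(p, g) {
  if (g > p) stop("g must not exceed p")
  cuts <- if (g > 1L) sort(sample.int(p - 1L, g - 1L)) else integer()
  as.integer(diff(c(0L, cuts, p)))
}

#' Generate a synthetic linear group-structured classification dataset
#'
#' Emulates a linear classification problem with known relevant feature
#' groups. Features are split into \code{g} contiguous groups of random sizes
#' (see [samplePartitionSizes()]); \code{nRelevant} groups, chosen uniformly
#' at random, are relevant. Every feature of an irrelevant group is i.i.d.
#' N(0,1). For each relevant group k a latent driver \code{z_k ~ N(0,1)} is
#' drawn per sample and every feature of the group is an independent noisy
#' copy \code{z_k + N(0,1)} (features of a relevant group therefore correlate
#' 0.5 pairwise and are jointly more informative than individually). Labels
#' are \code{y = 1} if \code{sum_k w_k z_k > 0} else 0, with weights
#' \code{w_k ~ U[0,1]}; then exactly \code{round(flipFraction * n)} labels,
#' chosen uniformly without replacement, are inverted.
#'
#' With \code{nRelevant = 0} the labels cannot be defined by the linear rule;
#' they are instead drawn i.i.d. Bernoulli(0.5), independent of all features
#' (the null configuration used for FWER-control checks).
#'
#' @param n number of samples.
#' @param p number of features (default 500).
#' @param g number of groups (default 50).
#' @param nRelevant number of relevant groups R (0 <= R <= g).
#' @param flipFraction label-noise rate in [0, 0.5) (default 0.01).
#' @param seed optional integer seed; the same seed reproduces the dataset
#'   bit for bit.
#' @return a [SyntheticBenchmark-class]
#' @examples
#' b <- syntheticBenchmark(n = 50, p = 40, g = 8, nRelevant = 2, seed = 7)
#' b@relevantGroups
#' @export
syntheticBenchmark <- function(n, p = 500L, g = 50L, nRelevant,
                               flipFraction = 0.01, seed = NULL) {
  stopifnot(nRelevant >= 0, nRelevant <= g, g <= p,
            flipFraction >= 0, flipFraction < 0.5, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  sizes <- samplePartitionSizes(p, g)
  ids <- paste0("G", seq_len(g))
  groups <- rep(ids, times = sizes)
  partition <- featurePartition(groups, groupOrder = ids)
  R <- as.integer(nRelevant)
  relevant <- if (R > 0L) sort(sample.int(g, R)) else integer()
  weights <- if (R > 0L) stats::runif(R) else numeric()
  latents <- matrix(stats::rnorm(n * R), nrow = n, ncol = R)

  x <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  members <- groupMembers(partition)
  for (j in seq_along(relevant)) {
    cols <- members[[relevant[j]]]
    x[, cols] <- x[, cols] + latents[, j]   # noisy copies of the latent
  }
  colnames(x) <- partition@featureIds

  if (R > 0L) {
    y <- as.integer(drop(latents %*% weights) > 0)  # sgn(0) maps to class 0
  } else {
    y <- as.integer(stats::runif(n) < 0.5)
  }
  nFlip <- as.integer(round(flipFraction * n))
  flipped <- if (nFlip > 0L) sort(sample.int(n, nFlip)) else integer()
  y[flipped] <- 1L - y[flipped]

  new("SyntheticBenchmark", x = x, y = y, partition = partition,
      relevantGroups = ids[relevant], weights = weights, latents = latents,
      flipped = flipped,
      spec = list(n = as.integer(n), p = as.integer(p), g = as.integer(g),
                  nRelevant = R, flipFraction = flipFraction, seed = seed))
}

setMethod("show", "SyntheticBenchmark", function(object) {
  s <- object@spec
  cat("SyntheticBenchmark: n =", s$n, ", p =", s$p, ", g =", s$g,
      ", relevant groups:", if (length(object@relevantGroups))
        paste(object@relevantGroups, collapse = ", ") else "(none)", "\n")
  cat(length(object@flipped), "label(s) flipped\n")
})

#' Write a synthetic benchmark to disk
#'
#' Writes the feature matrix (TSV with header), labels (single column),
#' partition table and a JSON ground-truth sidecar (relevant groups, weights,
#' flipped samples, generator parameters).
#'
#' @param bench a [SyntheticBenchmark-class]
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @return invisibly, the paths written
#' @export
writeSyntheticBenchmark <- function(bench, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".matrix.tsv", ".labels.txt",
                                           ".partition.tsv", ".truth.json")))
  utils::write.table(bench@x, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(as.character(bench@y), paths[2])
  writePartitionTable(bench@partition, paths[3])
  jsonlite::write_json(list(relevant_groups = bench@relevantGroups,
                            weights = bench@weights,
                            flipped = bench@flipped, spec = bench@spec),
                       paths[4], auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(paths)
}
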