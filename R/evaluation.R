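#' Precision and recall of a group selection
#'
#' Precision is TP/S with S the number of selected groups and TP the number of
#' truly relevant groups among them; by convention an empty selection has
#' precision 1 (no false discoveries). Recall is TP over the number of truly
#' relevant groups.
#'
#' @param selected character vector of selected group identifiers.
#' @param truth character vector of truly relevant group identifiers
#'   (non-empty).
#' @return named numeric vector \code{c(precision =, recall =)}
#' @export
precisionRecall <- function(selected, truth) {
  if (!length(truth)) stop("truth set is empty")
  tp <- sum(selected %in% truth)
  c(precision = if (length(selected)) tp / length(selected) else 1,
    recall = tp / length(truth))
}

#' Area under the precision-recall curve of a group ranking
#'
#' Walks the ranking, computing precision and recall of every top-k prefix
#' (k = 1..G), and integrates precision over recall with the trapezoid rule,
#' anchoring the curve at (recall 0, precision of the top-1 prefix). Equals 1
#' when all relevant groups occupy the top of the ranking, and is close to
#' R/g for a random ranking of g groups with R relevant.
#'
#' @param ranking character vector ordering all groups, best first.
#' @param truth non-empty character vector of relevant group identifiers.
#' @return AUPR in [0, 1]
#' @export
auprScore <- function(ranking, truth) {
  if (!length(truth)) stop("truth set is empty")
  hit <- cumsum(ranking %in% truth)
  kk <- seq_along(ranking)
  prec <- hit / kk
  rec <- hit / length(truth)
  rec0 <- c(0, rec)
  prec0 <- c(prec[1L], prec)
  sum(diff(rec0) * (utils::head(prec0, -1) + utils::tail(prec0, -1)) / 2)
}

#' Best recall at precision one and best precision at recall one
#'
#' \code{rec1} is the recall of the longest prefix of the ranking containing
#' no irrelevant group (the best a perfectly conservative selector could do);
#' \code{prec1} is the maximum precision over prefixes whose recall is 1 (the
#' best an exhaustive selector could do, always at least R/g).
#'
#' @inheritParams auprScore
#' @return named numeric vector \code{c(rec1 =, prec1 =)}
#' @export
rec1Prec1 <- function(ranking, truth) {
  if (!length(truth)) stop("truth set is empty")
  rel <- ranking %in% truth
  firstIrrel <- which(!rel)
  clean <- if (length(firstIrrel)) firstIrrel[1L] - 1L else length(ranking)
  rec1 <- clean / length(truth)
  hit <- cumsum(rel)
  full <- which(hit == length(truth))
  prec1 <- if (length(full)) max(hit[full] / full) else 0
  c(rec1 = min(rec1, 1), prec1 = prec1)
}

#' Misclassification rate in percent
#'
#' @param yTrue,yPred equal-length non-empty label vectors.
#' @return 100 * (number of disagreements) / n
#' @examples
#' ## a constant majority-class predictor on a 45-sample cohort with a
#' ## 22-sample minority class errs on 22/45 = 48.9% of samples
#' misclassificationRate(rep(c(0, 1), c(23, 22)), rep(0, 45))
#' @export
misclassificationRate <- function(yTrue, yPred) {
  if (!length(yTrue) || length(yTrue) != length(yPred))
    stop("label vectors must be non-empty and of equal length")
  100 * mean(yTrue != yPred)
}

#' Score a selection and a ranking against ground truth
#'
#' Convenience wrapper combining [precisionRecall()], [auprScore()] and
#' [rec1Prec1()] into a one-row data.frame.
#'
#' @param selected selected group identifiers.
#' @param ranking full ranking of all groups, best first.
#' @param truth relevant group identifiers.
#' @return data.frame with columns precision, recall, aupr, rec1, prec1,
#'   n_selected, n_relevant_selected
#' @export
assessSelection <- function(selected, ranking, truth) {
  pr <- precisionRecall(selected, truth)
  rp <- rec1Prec1(ranking, truth)
  data.frame(precision = pr[["precision"]], recall = pr[["recall"]],
             aupr = auprScore(ranking, truth),
             rec1 = rp[["rec1"]], prec1 = rp[["prec1"]],
             n_selected = length(selected),
             n_relevant_selected = sum(selected %in% truth))
}
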