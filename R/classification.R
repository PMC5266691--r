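#' @include AllClasses.R signal-features.R
NULL

#' Median-split labels for epochs from their parent clip's rating
#'
#' Epochs inherit the rating of their parent clip and are split at the
#' median into an exactly balanced low/high partition: epochs are ordered by
#' (clip value, clip id, epoch index) with a stable sort and the first half
#' is labeled \code{"low"}. Ties at the median are therefore resolved
#' deterministically, and with 900 epochs the split is always 450/450.
#'
#' @param epochInfo data.frame with \code{clip_id} (and optionally
#'   \code{epoch}) per epoch, as from \code{rowInfo()} of an epoch-level
#'   \linkS4class{BandPowerTensor}.
#' @param clipValues named numeric vector: one rating (or cluster score) per
#'   clip id.
#' @return Factor with levels \code{c("low", "high")}, one per epoch.
#' @export
medianSplitLabels <- function(epochInfo, clipValues) {
  if (!all(epochInfo$clip_id %in% names(clipValues)))
    stop("clipValues must cover every epoch's clip")
  v <- clipValues[epochInfo$clip_id]
  if (length(unique(v)) < 2L)
    stop("all clip values identical; no median split possible")
  ep <- epochInfo$epoch %||% seq_along(v)
  ord <- order(v, epochInfo$clip_id, ep, method = "radix")
  n <- length(v)
  lab <- character(n)
  lab[ord] <- rep(c("low", "high"), c(n %/% 2L, n - n %/% 2L))
  factor(lab, levels = c("low", "high"))
}

#' Median-split labels from a cluster score
#'
#' Identical mechanism to \code{\link{medianSplitLabels}} with the per-clip
#' cluster score in place of the item rating.
#'
#' @inheritParams medianSplitLabels
#' @param scores clips x clusters matrix (rownames = clip ids).
#' @param cluster cluster name or column index.
#' @export
clusterSplitLabels <- function(epochInfo, scores, cluster) {
  medianSplitLabels(epochInfo, stats::setNames(scores[, cluster],
                                               rownames(scores)))
}

#' Pairwise cluster labels from cluster-score differences
#'
#' A clip is labeled with cluster A when its A score exceeds its B score and
#' vice versa; exact ties are excluded with a warning. Epochs inherit their
#' clip's label, so class sizes need not be balanced.
#'
#' @param epochInfo epoch data.frame (see \code{\link{medianSplitLabels}}).
#' @param scores clips x clusters matrix (rownames = clip ids).
#' @param clusterA,clusterB the two cluster names to contrast.
#' @return List with \code{clipLabels} (named factor over clips),
#'   \code{labels} (factor over non-excluded epochs), \code{keep} (logical
#'   over epochs) and \code{classSizes} (clips per class).
#' @export
pairwiseClusterLabels <- function(epochInfo, scores, clusterA, clusterB) {
  diffs <- scores[, clusterA] - scores[, clusterB]
  if (all(diffs == 0)) stop("all clips tied between the two clusters")
  tied <- diffs == 0
  if (any(tied))
    warning(sum(tied), " clip(s) with exactly tied cluster scores excluded")
  clipLab <- factor(ifelse(diffs > 0, clusterA, clusterB),
                    levels = c(clusterA, clusterB))
  clipLab[tied] <- NA
  names(clipLab) <- rownames(scores)
  keep <- epochInfo$clip_id %in% rownames(scores)[!tied]
  labels <- clipLab[epochInfo$clip_id[keep]]
  list(clipLabels = clipLab, labels = droplevels(labels), keep = keep,
       classSizes = table(clipLab[!tied]))
}

#' Stratified 10-fold cross-validated margin classification
#'
#' Binary classification of epoch features with a linear-kernel support
#' vector machine (cost 1 by default). Folds are stratified at the epoch
#' level; within each fold, features are z-standardized with means and SDs
#' fitted on the training folds only. The reported accuracy is the mean of
#' the fold accuracies, in percent.
#'
#' @param features epochs x features numeric matrix (or an epoch-level
#'   \linkS4class{BandPowerTensor}).
#' @param labels binary factor, one label per epoch.
#' @param folds number of CV folds.
#' @param seed integer seed for the fold assignment.
#' @param kernel,cost passed to the SVM (\code{"linear"}, 1 by default).
#' @param protocol,task,participant metadata recorded in the result.
#' @return A \linkS4class{ClassificationResult}.
#' @export
crossvalClassify <- function(features, labels, folds = 10L, seed = 1L,
                             kernel = "linear", cost = 1,
                             protocol = "median_split", task = "",
                             participant = "") {
  if (is(features, "BandPowerTensor")) features <- featureMatrix(features)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("labels must be binary")
  if (min(table(labels)) < folds)
    stop("need at least `folds` epochs per class")
  set.seed(deriveSeed(seed, "folds"))
  foldId <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    foldId[idx] <- rep_len(seq_len(folds), length(idx))
  }
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- foldId != f
    mu <- colMeans(features[tr, , drop = FALSE])
    sdv <- apply(features[tr, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0] <- 1
    xtr <- scale(features[tr, , drop = FALSE], mu, sdv)
    xte <- scale(features[!tr, , drop = FALSE], mu, sdv)
    if (nlevels(droplevels(labels[tr])) < 2L)
      stop("degenerate single-class training fold")
    fit <- e1071::svm(xtr, labels[tr], kernel = kernel, cost = cost,
                      scale = FALSE)
    pred <- predict(fit, xte)
    acc[f] <- 100 * mean(pred == labels[!tr])
  }
  new("ClassificationResult", accuracy = mean(acc), foldAccuracies = acc,
      protocol = protocol, task = task, participant = participant,
      seed = as.integer(seed))
}

#' Grand-average classification
#'
#' Averages epoch features across participants at aligned (clip, epoch)
#' positions and runs the same cross-validated classification with labels
#' derived from cross-participant mean ratings or cluster scores.
#'
#' @param featureList list of epoch-level \linkS4class{BandPowerTensor}
#'   objects (one per participant) on identical epoch grids.
#' @param labels binary factor over the aligned epochs (computed by the
#'   caller from cross-participant mean ratings via the same split rules).
#' @param ... passed to \code{\link{crossvalClassify}}.
#' @return A \linkS4class{ClassificationResult} with
#'   \code{participant = "grand_average"}.
#' @export
grandAverageClassify <- function(featureList, labels, ...) {
  ga <- grandAverageFeatures(featureList)
  crossvalClassify(ga, labels, participant = "grand_average", ...)
}

#' Average epoch features across participants
#'
#' @param featureList list of epoch-level \linkS4class{BandPowerTensor}
#'   objects with identical (clip_id, epoch) row grids.
#' @return An epoch-level \linkS4class{BandPowerTensor} of the mean features.
#' @export
grandAverageFeatures <- function(featureList) {
  if (!length(featureList)) stop("empty feature list")
  ref <- rowInfo(featureList[[1L]])
  for (t in featureList[-1L]) {
    if (!identical(rowInfo(t)[, c("clip_id", "epoch")],
                   ref[, c("clip_id", "epoch")]))
      stop("epoch grids are misaligned across participants")
  }
  stack <- matrix(unlist(lapply(featureList, function(t) t@values)),
                  ncol = length(featureList))
  avg <- array(rowMeans(stack), dim = dim(featureList[[1L]]@values),
               dimnames = dimnames(featureList[[1L]]@values))
  initialize(featureList[[1L]], values = avg)
}
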