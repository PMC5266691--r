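#' @include generate-eeg.R signal-features.R neural-correlation.R
#' @include classification.R ratings-analysis.R
NULL

#' End-to-end correlation-topography pipeline on a synthetic study
#'
#' Generates (or reuses) each participant's EEG, extracts clip-level
#' baseline-corrected band power for all clips, correlates it with that
#' participant's ratings and averages the per-participant topographies.
#' Sessions are generated one at a time and discarded to keep memory flat.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param ratings a \linkS4class{RatingTable}.
#' @param effects an \linkS4class{EffectMap}.
#' @param participants subset of participant ids (default all).
#' @param preprocess apply \code{\link{preprocessSession}} before feature
#'   extraction (off by default: the generator's signals are band-limited
#'   and free of powerline noise by construction).
#' @param keepPerParticipant also return the per-participant maps.
#' @return The average \linkS4class{TopographyMap}, or a list with elements
#'   \code{average} and \code{maps} when \code{keepPerParticipant}.
#' @export
topographyPipeline <- function(design, ratings, effects,
                               participants = NULL, preprocess = FALSE,
                               keepPerParticipant = FALSE) {
  participants <- participants %||% participantIds(design)
  maps <- vector("list", length(participants))
  names(maps) <- participants
  for (pid in participants) {
    sess <- generateEEG(design, ratings, effects, participants = pid)[[1L]]
    if (preprocess) sess <- preprocessSession(sess)
    pw <- clipFeatures(sess, bands = effects@bands,
                       clipWindow = design@clipWindow,
                       baseline = design@baseline)
    maps[[pid]] <- correlatePowerRatings(pw, ratings, participant = pid)
  }
  avg <- averageTopography(maps)
  if (keepPerParticipant) list(average = avg, maps = maps) else avg
}

#' Epoch features for one participant of a synthetic study
#'
#' Generates the participant's session and returns the epoch-level
#' baseline-corrected band-power tensor restricted to the requested clip
#' categories (positive clips by default, yielding the 900 x 160 feature
#' set under the default design).
#'
#' @inheritParams topographyPipeline
#' @param participant one participant id.
#' @param categories clip categories to keep.
#' @return An epoch-level \linkS4class{BandPowerTensor}.
#' @export
participantEpochFeatures <- function(design, ratings, effects, participant,
                                     categories = "positive",
                                     preprocess = FALSE) {
  sess <- generateEEG(design, ratings, effects,
                      participants = participant)[[1L]]
  if (preprocess) sess <- preprocessSession(sess)
  keep <- design@clips$clip_id[design@clips$category %in% categories]
  epochFeatures(sess, bands = effects@bands, clipWindow = design@clipWindow,
                baseline = design@baseline, clipIds = keep)
}

#' All labeling protocols for one participant's epoch features
#'
#' Runs the item median-split, cluster-score median-split and pairwise
#' cluster protocols on one epoch tensor and returns one accuracy per task.
#'
#' @param features epoch-level \linkS4class{BandPowerTensor}.
#' @param clipRatings clips x items matrix for this participant (or the
#'   cross-participant means for the grand-average pipeline).
#' @param scores clips x clusters score matrix on the same scale.
#' @param items item tasks to run (default none).
#' @param clusters cluster tasks to run (default none).
#' @param pairs list of length-2 cluster name vectors (default none).
#' @param folds,seed CV parameters.
#' @param participant id recorded in the results.
#' @return List of \linkS4class{ClassificationResult} objects, named
#'   \code{item:<name>}, \code{cluster:<name>}, \code{pair:<A>_vs_<B>}.
#' @export
classificationTasks <- function(features, clipRatings, scores = NULL,
                                items = character(), clusters = character(),
                                pairs = list(), folds = 10L, seed = 1L,
                                participant = "") {
  info <- rowInfo(features)
  fm <- featureMatrix(features)
  res <- list()
  for (it in items) {
    lab <- medianSplitLabels(info, stats::setNames(clipRatings[, it],
                                                   rownames(clipRatings)))
    res[[paste0("item:", it)]] <-
      crossvalClassify(fm, lab, folds, seed, protocol = "item_median_split",
                       task = it, participant = participant)
  }
  for (cl in clusters) {
    lab <- clusterSplitLabels(info, scores, cl)
    res[[paste0("cluster:", cl)]] <-
      crossvalClassify(fm, lab, folds, seed,
                       protocol = "cluster_median_split", task = cl,
                       participant = participant)
  }
  for (pr in pairs) {
    pw <- pairwiseClusterLabels(info, scores, pr[1L], pr[2L])
    res[[paste0("pair:", pr[1L], "_vs_", pr[2L])]] <-
      crossvalClassify(fm[pw$keep, , drop = FALSE], pw$labels, folds, seed,
                       protocol = "pairwise_cluster",
                       task = paste(pr, collapse = "_vs_"),
                       participant = participant)
  }
  res
}

#' Assemble an accuracy table from classification results
#'
#' @param resultsByParticipant named list (participant -> list of
#'   \linkS4class{ClassificationResult}).
#' @param grandResults optional list of grand-average results.
#' @return data.frame with one row per participant plus \code{Mean} and
#'   \code{Grand_Average} rows, one column per task, accuracies in percent
#'   rounded to 0.1.
#' @export
accuracyTable <- function(resultsByParticipant, grandResults = NULL) {
  tasks <- names(resultsByParticipant[[1L]])
  m <- t(vapply(resultsByParticipant,
                function(rs) vapply(rs, accuracy, 0)[tasks],
                numeric(length(tasks))))
  out <- as.data.frame(round(m, 1L))
  names(out) <- tasks
  out <- rbind(out, Mean = round(colMeans(m), 1L))
  if (!is.null(grandResults))
    out <- rbind(out, Grand_Average = round(vapply(grandResults, accuracy,
                                                   0)[tasks], 1L))
  cbind(participant = rownames(out), out, stringsAsFactors = FALSE)
}
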