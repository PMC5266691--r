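#' @include AllClasses.R
NULL

#' Accessors for the core containers
#'
#' Small generic accessors so user code never touches slots directly.
#'
#' @param object one of the package's S4 containers.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("itemNames", function(object) standardGeneric("itemNames"))
#' @rdname accessors
#' @export
setGeneric("clipIds", function(object) standardGeneric("clipIds"))
#' @rdname accessors
#' @export
setGeneric("participantIds", function(object) standardGeneric("participantIds"))
#' @rdname accessors
#' @export
setGeneric("ratingValues", function(object) standardGeneric("ratingValues"))
#' @rdname accessors
#' @export
setGeneric("bandNames", function(object) standardGeneric("bandNames"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("rowInfo", function(object) standardGeneric("rowInfo"))
#' @rdname accessors
#' @export
setGeneric("stressValue", function(object) standardGeneric("stressValue"))
#' @rdname accessors
#' @export
setGeneric("clusterAssignment", function(object) standardGeneric("clusterAssignment"))
#' @rdname accessors
#' @export
setGeneric("clusterScoreMatrix", function(object) standardGeneric("clusterScoreMatrix"))
#' @rdname accessors
#' @export
setGeneric("embeddingCoords", function(object) standardGeneric("embeddingCoords"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setGeneric("foldAccuracies", function(object) standardGeneric("foldAccuracies"))
#' @rdname accessors
#' @export
setGeneric("corrValues", function(object) standardGeneric("corrValues"))
#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setGeneric("sessionEvents", function(object) standardGeneric("sessionEvents"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
setMethod("itemNames", "RatingTable", function(object) dimnames(object@values)[[3L]])
#' @rdname accessors
setMethod("itemNames", "StudyDesign", function(object) object@items)
#' @rdname accessors
setMethod("itemNames", "TopographyMap", function(object) dimnames(object@r)[[3L]])
#' @rdname accessors
setMethod("clipIds", "RatingTable", function(object) dimnames(object@values)[[2L]])
#' @rdname accessors
setMethod("clipIds", "StudyDesign", function(object) object@clips$clip_id)
#' @rdname accessors
setMethod("clipIds", "BandPowerTensor", function(object) unique(object@rowData$clip_id))
#' @rdname accessors
setMethod("participantIds", "RatingTable", function(object) dimnames(object@values)[[1L]])
#' @rdname accessors
setMethod("participantIds", "StudyDesign", function(object)
  sprintf("P%02d", seq_len(object@nParticipants)))
#' @rdname accessors
setMethod("ratingValues", "RatingTable", function(object) object@values)
#' @rdname accessors
setMethod("bandNames", "BandPowerTensor", function(object) object@bands$name)
#' @rdname accessors
setMethod("bandNames", "TopographyMap", function(object) dimnames(object@r)[[2L]])
#' @rdname accessors
setMethod("channelNames", "EEGSession", function(object) object@channelLabels)
#' @rdname accessors
setMethod("channelNames", "BandPowerTensor", function(object) dimnames(object@values)[[2L]])
#' @rdname accessors
setMethod("channelNames", "TopographyMap", function(object) dimnames(object@r)[[1L]])
#' @rdname accessors
setMethod("rowInfo", "BandPowerTensor", function(object) object@rowData)
#' @rdname accessors
setMethod("stressValue", "ClusterModel", function(object) object@stress)
#' @rdname accessors
setMethod("clusterAssignment", "ClusterModel", function(object) object@assignment)
#' @rdname accessors
setMethod("clusterScoreMatrix", "ClusterModel", function(object) object@clusterScores)
#' @rdname accessors
setMethod("embeddingCoords", "ClusterModel", function(object) object@embedding)
#' @rdname accessors
setMethod("accuracy", "ClassificationResult", function(object) object@accuracy)
#' @rdname accessors
setMethod("foldAccuracies", "ClassificationResult", function(object) object@foldAccuracies)
#' @rdname accessors
setMethod("corrValues", "TopographyMap", function(object) object@r)
#' @rdname accessors
setMethod("signalMatrix", "EEGSession", function(object) object@signals)
#' @rdname accessors
setMethod("sessionEvents", "EEGSession", function(object) object@events)
#' @rdname accessors
setMethod("samplingRate", "EEGSession", function(object) object@samplingRate)

#' Flatten an epoch/clip tensor to a rows x (channels * bands) matrix
#'
#' Channel varies fastest within each band block; with the default 32-channel
#' montage and five bands this yields the 160-dimensional feature vectors
#' used for classification.
#'
#' @rdname accessors
setMethod("featureMatrix", "BandPowerTensor", function(object) {
  d <- dim(object@values)
  m <- matrix(object@values, nrow = d[1L])
  colnames(m) <- as.vector(outer(dimnames(object@values)[[2L]],
                                 dimnames(object@values)[[3L]], paste, sep = "."))
  m
})

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", object@nParticipants, "participants,",
      nrow(object@clips), "clips (",
      sum(object@clips$category == "positive"), "positive /",
      sum(object@clips$category == "negative"), "negative /",
      sum(object@clips$category == "neutral"), "neutral ),",
      length(object@channels), "channels @", object@samplingRate, "Hz\n")
  cat("  analysis window:", object@clipWindow, "s; baseline:",
      object@baseline, "s; seed:", object@seed, "\n")
})

setMethod("show", "RatingTable", function(object) {
  d <- dim(object@values)
  cat("RatingTable:", d[1L], "participants x", d[2L], "clips x",
      d[3L], "items (Likert 1-7)\n")
})

setMethod("show", "EEGSession", function(object) {
  cat("EEGSession", object@participantId, ":",
      nrow(object@signals), "channels x", ncol(object@signals),
      "samples @", object@samplingRate, "Hz;",
      nrow(object@events), "clip events\n")
})

setMethod("show", "BandPowerTensor", function(object) {
  d <- dim(object@values)
  cat("BandPowerTensor (", object@level, "level ):", d[1L], "rows x",
      d[2L], "channels x", d[3L], "bands;",
      if (object@baselineCorrected) "baseline-corrected" else "raw", "\n")
})

setMethod("show", "TopographyMap", function(object) {
  d <- dim(object@r)
  cat("TopographyMap (", object@level, "):", d[1L], "channels x", d[2L],
      "bands x", d[3L], "items; n =", object@nClips, "clips\n")
})

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel:", nrow(object@embedding), "items in",
      ncol(object@embedding), "dims; Kruskal stress-1 =",
      signif(object@stress, 3), "\n")
  if (length(object@assignment)) {
    for (cl in unique(object@assignment))
      cat("  ", cl, ":", paste(names(object@assignment)[object@assignment == cl],
                               collapse = ", "), "\n")
  }
})

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("ClassificationResult [%s | %s | %s]: %.1f%% (10-fold range %.1f-%.1f)\n",
              object@participant, object@protocol, object@task,
              object@accuracy, min(object@foldAccuracies),
              max(object@foldAccuracies)))
})
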