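#' @import methods
NULL

#' Study design for a film-clip EEG emotion experiment
#'
#' Describes the experimental layout emulated by the synthetic-data
#' generator: participants, film clips (with category and target emotion),
#' rating items, EEG montage and the analysis windows.
#'
#' @slot nParticipants number of participants.
#' @slot clips data.frame with columns \code{clip_id}, \code{category}
#'   (\code{"positive"}, \code{"negative"} or \code{"neutral"}),
#'   \code{target_emotion} (one of the ten positive items, or \code{NA}) and
#'   \code{duration_s}.
#' @slot items ordered character vector of the 14 rating items (ten positive
#'   emotions plus arousal, valence, familiarity, liking).
#' @slot samplingRate EEG sampling rate in Hz.
#' @slot channels ordered 10-20 channel labels.
#' @slot clipWindow seconds of clip-final EEG used for analysis.
#' @slot baseline seconds of pre-onset EEG used as spectral baseline.
#' @slot interClipGap seconds of rest signal generated between clips; must be
#'   at least \code{baseline}.
#' @slot seed integer master seed for the whole study.
#' @exportClass StudyDesign
setClass("StudyDesign", representation(
  nParticipants = "integer",
  clips = "data.frame",
  items = "character",
  samplingRate = "numeric",
  channels = "character",
  clipWindow = "numeric",
  baseline = "numeric",
  interClipGap = "numeric",
  seed = "integer"
))

setValidity("StudyDesign", function(object) {
  msg <- character()
  need <- c("clip_id", "category", "target_emotion", "duration_s")
  if (!all(need %in% names(object@clips)))
    msg <- c(msg, "clips must have columns clip_id, category, target_emotion, duration_s")
  else {
    if (anyDuplicated(object@clips$clip_id))
      msg <- c(msg, "clip ids must be unique")
    if (!all(object@clips$category %in% c("positive", "negative", "neutral")))
      msg <- c(msg, "clip categories must be positive/negative/neutral")
    pos <- object@clips$category == "positive"
    if (any(!object@clips$target_emotion[pos] %in% positiveItems()))
      msg <- c(msg, "positive clips need a target_emotion among the ten positive items")
    if (any(object@clips$duration_s < object@clipWindow))
      msg <- c(msg, "all clip durations must be >= clipWindow")
  }
  if (anyDuplicated(object@channels)) msg <- c(msg, "channel labels must be unique")
  if (object@nParticipants < 1L) msg <- c(msg, "need at least one participant")
  if (object@interClipGap < object@baseline)
    msg <- c(msg, "interClipGap must be >= baseline so a baseline window exists")
  if (length(msg)) msg else TRUE
})

#' Latent rating model with three planted emotion clusters
#'
#' Parameterizes how subjective ratings are generated: each clip carries a
#' latent activation for the encouragement / playfulness / harmony clusters,
#' items load onto their own cluster, a clip's target emotion receives an
#' extra boost, and participant-level noise controls inter-rater reliability.
#'
#' @slot clusterAssignment named character vector mapping the ten positive
#'   items to \code{"encouragement"}, \code{"playfulness"} or \code{"harmony"}.
#' @slot loadings ten-item by three-cluster nonnegative loading matrix.
#' @slot participantNoiseSd rater noise (rating-scale units); drives ICC down.
#' @slot itemNoiseSd clip-by-item latent noise shared across participants.
#' @slot targetBoost mean rating increment on a clip's target emotion.
#' @slot clusterActivationSd spread of the per-clip cluster activations.
#' @slot clusterBoost activation increment for the target emotion's cluster.
#' @slot baseRating latent grand mean on the 7-point scale.
#' @exportClass LatentEmotionModel
setClass("LatentEmotionModel", representation(
  clusterAssignment = "character",
  loadings = "matrix",
  participantNoiseSd = "numeric",
  itemNoiseSd = "numeric",
  targetBoost = "numeric",
  clusterActivationSd = "numeric",
  clusterBoost = "numeric",
  baseRating = "numeric"
))

setValidity("LatentEmotionModel", function(object) {
  msg <- character()
  if (!setequal(names(object@clusterAssignment), positiveItems()))
    msg <- c(msg, "clusterAssignment must cover exactly the ten positive items")
  if (!all(object@clusterAssignment %in% clusterNames()))
    msg <- c(msg, "cluster labels must be encouragement/playfulness/harmony")
  if (any(object@loadings < 0))
    msg <- c(msg, "loadings of the positive items must be nonnegative")
  if (!identical(sort(rownames(object@loadings)), sort(positiveItems())))
    msg <- c(msg, "loadings rows must be the ten positive items")
  if (!identical(colnames(object@loadings), clusterNames()))
    msg <- c(msg, "loadings columns must be the three clusters")
  if (length(msg)) msg else TRUE
})

#' Planted channel-by-band-by-item effect map for EEG synthesis
#'
#' The linear model behind the generator: band power of channel \code{ch} in
#' band \code{b} during a clip is \code{basePower[ch,b] +
#' sum_i beta[ch,b,i] * z(rating_i) + noise}.
#'
#' @slot beta channels x bands x items array of effect coefficients
#'   (power units per rating SD).
#' @slot basePower channels x bands nonnegative baseline band power
#'   (per-bin average, uV^2).
#' @slot powerNoiseSd SD of the clip-level power noise (same units).
#' @slot bands data.frame of band definitions (name, f_lo, f_hi).
#' @exportClass EffectMap
setClass("EffectMap", representation(
  beta = "array",
  basePower = "matrix",
  powerNoiseSd = "numeric",
  bands = "data.frame"
))

setValidity("EffectMap", function(object) {
  msg <- character()
  if (length(dim(object@beta)) != 3L)
    msg <- c(msg, "beta must be a channels x bands x items array")
  if (!all(is.finite(object@beta))) msg <- c(msg, "beta must be finite")
  if (any(object@basePower < 0)) msg <- c(msg, "basePower must be nonnegative")
  if (!identical(dim(object@beta)[1:2], dim(object@basePower)))
    msg <- c(msg, "beta and basePower disagree on channels/bands")
  if (length(msg)) msg else TRUE
})

#' Participants x clips x items table of Likert ratings
#'
#' @slot values integer array (participants x clips x items) of 1-7 ratings,
#'   with dimnames.
#' @exportClass RatingTable
setClass("RatingTable", representation(values = "array"))

setValidity("RatingTable", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be participants x clips x items")
  if (anyNA(object@values)) msg <- c(msg, "rating table must be complete")
  else if (any(object@values < 1L | object@values > 7L))
    msg <- c(msg, "ratings must lie in [1, 7]")
  if (is.null(dimnames(object@values)) || any(vapply(dimnames(object@values), is.null, TRUE)))
    msg <- c(msg, "values needs participant/clip/item dimnames")
  if (length(msg)) msg else TRUE
})

#' One participant's continuous EEG with clip-onset events
#'
#' @slot signals channels x samples matrix, microvolts.
#' @slot samplingRate Hz.
#' @slot channelLabels ordered channel names (rownames of \code{signals}).
#' @slot events data.frame with \code{clip_id}, \code{onset_sample},
#'   \code{offset_sample} (1-based, inclusive).
#' @slot participantId identifier.
#' @exportClass EEGSession
setClass("EEGSession", representation(
  signals = "matrix",
  samplingRate = "numeric",
  channelLabels = "character",
  events = "data.frame",
  participantId = "character"
))

setValidity("EEGSession", function(object) {
  msg <- character()
  if (nrow(object@signals) != length(object@channelLabels))
    msg <- c(msg, "one label per signal row required")
  ev <- object@events
  if (!all(c("clip_id", "onset_sample", "offset_sample") %in% names(ev)))
    msg <- c(msg, "events need clip_id, onset_sample, offset_sample")
  else {
    if (any(ev$onset_sample >= ev$offset_sample))
      msg <- c(msg, "event onsets must precede offsets")
    if (any(ev$offset_sample > ncol(object@signals)))
      msg <- c(msg, "event offsets exceed the recording")
  }
  if (length(msg)) msg else TRUE
})

#' Clip- or epoch-level band-power features
#'
#' Rows are clips (clip level) or 1-s epochs (epoch level); the remaining
#' axes are channels and frequency bands. Row metadata tracks the parent
#' clip and epoch index so labels can be propagated from clip ratings.
#'
#' @slot values rows x channels x bands array of band power (per-bin
#'   average, uV^2; may be negative after baseline correction).
#' @slot rowData data.frame with \code{clip_id} and, at epoch level,
#'   \code{epoch} (1-based index within the clip window).
#' @slot bands band definition data.frame.
#' @slot level \code{"clip"} or \code{"epoch"}.
#' @slot baselineCorrected logical flag.
#' @exportClass BandPowerTensor
setClass("BandPowerTensor", representation(
  values = "array",
  rowData = "data.frame",
  bands = "data.frame",
  level = "character",
  baselineCorrected = "logical"
))

setValidity("BandPowerTensor", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be rows x channels x bands")
  if (nrow(object@rowData) != dim(object@values)[1L])
    msg <- c(msg, "rowData must describe every row")
  if (!object@level %in% c("clip", "epoch"))
    msg <- c(msg, "level must be 'clip' or 'epoch'")
  if (!all(is.finite(object@values))) msg <- c(msg, "band power must be finite")
  if (length(msg)) msg else TRUE
})

#' Channel x band x item correlation topography
#'
#' @slot r channels x bands x items array of Pearson correlations between
#'   baseline-corrected band power and ratings (NA where undefined).
#' @slot nClips clips entering each correlation.
#' @slot nMaps number of participant maps averaged (1 for a single map).
#' @slot level \code{"participant"}, \code{"average"} or \code{"truth"}.
#' @exportClass TopographyMap
setClass("TopographyMap", representation(
  r = "array",
  nClips = "integer",
  nMaps = "integer",
  level = "character"
))

setValidity("TopographyMap", function(object) {
  msg <- character()
  if (length(dim(object@r)) != 3L)
    msg <- c(msg, "r must be channels x bands x items")
  vals <- object@r[is.finite(object@r)]
  if (object@level != "truth" && length(vals) && max(abs(vals)) > 1 + 1e-8)
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Non-metric MDS embedding and cluster structure of the positive emotions
#'
#' @slot embedding items x dims coordinates.
#' @slot stress Kruskal Stress-1 on the [0, 1] scale.
#' @slot assignment named character vector item -> cluster label (possibly
#'   empty until clusters are assigned).
#' @slot clusterScores clips x clusters matrix of mean z-transformed
#'   ratings (possibly 0-row until computed).
#' @exportClass ClusterModel
setClass("ClusterModel", representation(
  embedding = "matrix",
  stress = "numeric",
  assignment = "character",
  clusterScores = "matrix"
))

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (!is.na(object@stress) && (object@stress < 0 || object@stress > 1))
    msg <- c(msg, "stress must lie in [0, 1]")
  if (length(object@assignment) &&
      !setequal(names(object@assignment), rownames(object@embedding)))
    msg <- c(msg, "assignment must cover exactly the embedded items")
  if (length(msg)) msg else TRUE
})

#' Cross-validated binary classification result
#'
#' @slot accuracy mean fold accuracy, percent.
#' @slot foldAccuracies per-fold accuracies, percent.
#' @slot protocol labeling protocol used.
#' @slot task item / cluster / pair the labels came from.
#' @slot participant participant id or \code{"grand_average"}.
#' @slot seed fold-assignment seed.
#' @exportClass ClassificationResult
setClass("ClassificationResult", representation(
  accuracy = "numeric",
  foldAccuracies = "numeric",
  protocol = "character",
  task = "character",
  participant = "character",
  seed = "integer"
))

setValidity("ClassificationResult", function(object) {
  msg <- character()
  if (object@accuracy < 0 || object@accuracy > 100)
    msg <- c(msg, "accuracy must be a percentage")
  if (abs(object@accuracy - mean(object@foldAccuracies)) > 1e-8)
    msg <- c(msg, "accuracy must equal the mean fold accuracy")
  if (length(msg)) msg else TRUE
})
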