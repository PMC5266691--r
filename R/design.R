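#' @include AllClasses.R
NULL

#' The ten positive emotion items
#'
#' Item names in the fixed (alphabetical) order used throughout the package.
#'
#' @return Character vector of length 10.
#' @export
positiveItems <- function() {
  c("amusement", "awe", "gratitude", "hope", "inspiration",
    "interest", "joy", "love", "pride", "serenity")
}

#' The three emotion cluster labels
#' @return Character vector of length 3.
#' @export
clusterNames <- function() c("encouragement", "playfulness", "harmony")

#' Published item-to-cluster assignment
#'
#' Encouragement: awe, gratitude, hope, inspiration, pride. Playfulness:
#' amusement, interest, joy. Harmony: love, serenity.
#'
#' @return Named character vector mapping the ten positive items to clusters.
#' @export
defaultClusterAssignment <- function() {
  c(awe = "encouragement", gratitude = "encouragement", hope = "encouragement",
    inspiration = "encouragement", pride = "encouragement",
    amusement = "playfulness", interest = "playfulness", joy = "playfulness",
    love = "harmony", serenity = "harmony")[positiveItems()]
}

#' All 14 rating items
#' @return Character vector: ten positive emotions, then arousal, valence,
#'   familiarity, liking.
#' @export
defaultItems <- function() {
  c(positiveItems(), "arousal", "valence", "familiarity", "liking")
}

#' The 32-channel 10-20 montage
#' @return Character vector of 32 channel labels.
#' @export
standardChannels <- function() {
  c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8",
    "FC1", "FC2", "FC5", "FC6",
    "Cz", "C3", "C4", "T3", "T4",
    "CP1", "CP2", "CP5", "CP6",
    "Pz", "P3", "P4", "P7", "P8",
    "PO3", "PO4", "PO7", "PO8",
    "Oz", "O1", "O2")
}

# scalp regions used by the effect presets
centralChannels <- function() c("FC1", "FC2", "Cz", "C3", "C4", "CP1", "CP2")
parietoOccipitalChannels <- function() {
  c("Pz", "P3", "P4", "P7", "P8", "PO3", "PO4", "PO7", "PO8", "Oz", "O1", "O2")
}
leftFrontalChannels <- function() c("Fp1", "F3", "F7")
rightFrontalChannels <- function() c("Fp2", "F4", "F8")

#' Default analysis frequency bands
#'
#' theta 3-7, low alpha 8-10, alpha 8-13, beta 14-29 and gamma 30-47 Hz
#' (inclusive edges). Note low alpha is nested inside alpha.
#'
#' @return data.frame with columns \code{name}, \code{f_lo}, \code{f_hi}.
#' @export
defaultBands <- function() {
  data.frame(name = c("theta", "low_alpha", "alpha", "beta", "gamma"),
             f_lo = c(3, 8, 8, 14, 30),
             f_hi = c(7, 10, 13, 29, 47),
             stringsAsFactors = FALSE)
}

#' Default film-clip set: 30 positive (3 per emotion), 6 negative, 1 neutral
#'
#' Clip durations are drawn once from a normal distribution with mean 69 s
#' and SD 24 s truncated to [30, 129] s, matching typical film-stimulus
#' variability; a fixed draw seed keeps the clip table reproducible.
#'
#' @param seed integer controlling the duration draw.
#' @param durationRange numeric length-2 truncation bounds in seconds.
#' @return data.frame usable as the \code{clips} slot of a
#'   \linkS4class{StudyDesign}.
#' @export
defaultClips <- function(seed = 20L, durationRange = c(30, 129)) {
  pos <- positiveItems()
  ids <- c(sprintf("%s_%d", rep(pos, each = 3L), 1:3),
           sprintf("negative_%d", 1:6), "neutral_1")
  category <- c(rep("positive", 30L), rep("negative", 6L), "neutral")
  target <- c(rep(pos, each = 3L), rep(NA_character_, 7L))
  n <- length(ids)
  set.seed(deriveSeed(seed, "clip_durations"))
  dur <- round(stats::rnorm(n, 69, 24))
  dur <- pmin(pmax(dur, durationRange[1L]), durationRange[2L])
  data.frame(clip_id = ids, category = category, target_emotion = target,
             duration_s = dur, stringsAsFactors = FALSE)
}

#' Construct a study design
#'
#' Defaults emulate the study layout: 20 participants, 37 clips (30 positive
#' = 3 per target emotion, 6 negative, 1 neutral), 14 rating items, 32-channel
#' 10-20 montage at 250 Hz, a 30-s clip-final analysis window and a 5-s
#' pre-onset baseline.
#'
#' @param nParticipants number of participants.
#' @param clips clip table as from \code{\link{defaultClips}}.
#' @param items ordered rating item names.
#' @param samplingRate Hz.
#' @param channels channel labels.
#' @param clipWindow analysis window, seconds.
#' @param baseline baseline window, seconds.
#' @param interClipGap generated rest between clips, seconds (>= baseline).
#' @param seed master seed for the study.
#' @return A \linkS4class{StudyDesign}.
#' @examples
#' design <- studyDesign(seed = 1)
#' design
#' @export
studyDesign <- function(nParticipants = 20L,
                        clips = defaultClips(seed = seed),
                        items = defaultItems(),
                        samplingRate = 250,
                        channels = standardChannels(),
                        clipWindow = 30,
                        baseline = 5,
                        interClipGap = 7,
                        seed = 1L) {
  new("StudyDesign", nParticipants = as.integer(nParticipants), clips = clips,
      items = items, samplingRate = samplingRate, channels = channels,
      clipWindow = clipWindow, baseline = baseline,
      interClipGap = interClipGap, seed = as.integer(seed))
}

#' Construct the latent rating model
#'
#' The defaults plant the three-cluster structure (encouragement /
#' playfulness / harmony) with moderate rater noise, giving high inter-rater
#' reliability and clearly elevated target-emotion ratings, while leaving
#' visible overlap between same-cluster items.
#'
#' @param clusterAssignment item -> cluster map for the ten positive items.
#' @param loadings 10 x 3 nonnegative loading matrix (rows = positive items,
#'   columns = clusters); default is an indicator matrix.
#' @param participantNoiseSd rater noise SD (rating units).
#' @param itemNoiseSd clip-by-item latent noise SD shared across raters.
#' @param targetBoost latent boost on a clip's target emotion.
#' @param clusterActivationSd SD of per-clip cluster activations.
#' @param clusterBoost activation boost for the target emotion's cluster.
#' @param baseRating latent grand mean.
#' @return A \linkS4class{LatentEmotionModel}.
#' @export
latentEmotionModel <- function(clusterAssignment = defaultClusterAssignment(),
                               loadings = NULL,
                               participantNoiseSd = 0.8,
                               itemNoiseSd = 0.3,
                               targetBoost = 1.5,
                               clusterActivationSd = 0.8,
                               clusterBoost = 1.2,
                               baseRating = 2.5) {
  if (is.null(loadings)) {
    loadings <- matrix(0, length(clusterAssignment), length(clusterNames()),
                       dimnames = list(names(clusterAssignment), clusterNames()))
    loadings[cbind(names(clusterAssignment), clusterAssignment)] <- 1
  }
  new("LatentEmotionModel", clusterAssignment = clusterAssignment,
      loadings = loadings, participantNoiseSd = participantNoiseSd,
      itemNoiseSd = itemNoiseSd, targetBoost = targetBoost,
      clusterActivationSd = clusterActivationSd, clusterBoost = clusterBoost,
      baseRating = baseRating)
}

#' A structureless null rating model
#'
#' All planted structure is switched off (no cluster activations, no target
#' boost, no shared clip-by-item noise): items are exchangeable and only
#' independent rater noise remains. Used to check type-I error control of
#' the manipulation check. The latent mean sits mid-scale so Likert clipping
#' stays symmetric.
#'
#' @param participantNoiseSd rater noise SD.
#' @return A \linkS4class{LatentEmotionModel}.
#' @export
nullLatentEmotionModel <- function(participantNoiseSd = 0.8) {
  latentEmotionModel(participantNoiseSd = participantNoiseSd,
                     itemNoiseSd = 0, targetBoost = 0,
                     clusterActivationSd = 0, clusterBoost = 0,
                     baseRating = 4)
}

#' Construct a planted effect map
#'
#' \code{preset = "planted"} encodes the qualitative correlation
#' topographies the analysis should recover: encouragement emotions gain
#' central alpha and beta power, playfulness emotions gain theta globally and
#' gamma broadly, harmony emotions gain parieto-occipital alpha; arousal is
#' tied to reduced parieto-occipital alpha and valence to a frontal alpha
#' asymmetry (right minus left). Encouragement and harmony carry small
#' negative gamma effects. \code{preset = "null"} plants nothing.
#'
#' @param preset \code{"planted"} or \code{"null"}.
#' @param channels channel labels.
#' @param items rating item names.
#' @param bands band definition table.
#' @param powerNoiseSd SD of clip-level power noise (uV^2 per bin).
#' @param basePower optional channels x bands matrix; default follows a
#'   1/f-like profile with an alpha peak (theta 8, low alpha 10, alpha 10,
#'   beta 4, gamma 1.5 uV^2 per bin).
#' @return An \linkS4class{EffectMap}.
#' @examples
#' em <- effectMap("planted")
#' dim(em@beta)
#' @export
effectMap <- function(preset = c("planted", "null"),
                      channels = standardChannels(),
                      items = defaultItems(),
                      bands = defaultBands(),
                      powerNoiseSd = 1.0,
                      basePower = NULL) {
  preset <- match.arg(preset)
  bn <- bands$name
  if (is.null(basePower)) {
    base <- c(theta = 8, low_alpha = 10, alpha = 10, beta = 4, gamma = 1.5)[bn]
    base[is.na(base)] <- 5
    basePower <- matrix(rep(base, each = length(channels)),
                        nrow = length(channels),
                        dimnames = list(channels, bn))
  }
  beta <- array(0, dim = c(length(channels), length(bn), length(items)),
                dimnames = list(channels, bn, items))
  if (preset == "planted") {
    assign <- defaultClusterAssignment()
    enc <- names(assign)[assign == "encouragement" & names(assign) %in% items]
    pla <- names(assign)[assign == "playfulness" & names(assign) %in% items]
    har <- names(assign)[assign == "harmony" & names(assign) %in% items]
    ctr <- intersect(centralChannels(), channels)
    po <- intersect(parietoOccipitalChannels(), channels)
    lf <- intersect(leftFrontalChannels(), channels)
    rf <- intersect(rightFrontalChannels(), channels)
    setBeta <- function(chs, bds, its, value) {
      bds <- intersect(bds, bn)
      if (length(chs) && length(bds) && length(its))
        beta[chs, bds, its] <<- value
    }
    # encouragement: central alpha and beta increase, mild gamma decrease
    setBeta(ctr, c("alpha", "low_alpha"), enc, 0.8)
    setBeta(ctr, "beta", enc, 0.4)
    setBeta(ctr, "gamma", enc, -0.15)
    # playfulness: global theta increase, broad gamma increase
    setBeta(channels, "theta", pla, 0.9)
    setBeta(channels, "gamma", pla, 0.25)
    # harmony: parieto-occipital alpha increase, mild gamma decrease
    setBeta(po, c("alpha", "low_alpha"), har, 1.0)
    setBeta(po, "gamma", har, -0.15)
    # arousal: parieto-occipital alpha decrease
    setBeta(po, c("alpha", "low_alpha"), intersect("arousal", items), -0.9)
    # valence: frontal alpha asymmetry (right up, left down)
    setBeta(rf, c("alpha", "low_alpha"), intersect("valence", items), 0.6)
    setBeta(lf, c("alpha", "low_alpha"), intersect("valence", items), -0.6)
  }
  new("EffectMap", beta = beta, basePower = basePower,
      powerNoiseSd = powerNoiseSd, bands = bands)
}

#' Schematic 2-D positions of the 32-channel montage
#'
#' Top-view unit-disc coordinates (x toward the right ear, y toward the
#' nasion) for the default montage, shipped as a packaged CSV. Intended for
#' scalp-map rendering of \linkS4class{TopographyMap} objects; no numerical
#' analysis depends on these coordinates.
#'
#' @return data.frame with columns \code{channel}, \code{x}, \code{y}.
#' @export
channelPositions <- function() {
  utils::read.csv(system.file("extdata", "channel_positions_1020.csv",
                              package = "emospect"),
                  stringsAsFactors = FALSE)
}
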