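#' @include design.R
NULL

# Latent clip-level structure shared by every participant: per-clip cluster
# activations, item means, and the four appraisal dimensions.
latentClipMeans <- function(design, model) {
  clips <- design@clips
  items <- design@items
  pos <- positiveItems()
  if (!all(pos %in% items))
    stop("design items must include the ten positive emotions")
  if (!setequal(names(model@clusterAssignment), pos))
    stop("latent model and design disagree on the positive item set")
  nClips <- nrow(clips)
  act <- matrix(stats::rnorm(nClips * 3L, 0, model@clusterActivationSd),
                nClips, 3L, dimnames = list(clips$clip_id, clusterNames()))
  nonpos <- clips$category != "positive"
  # control clips sit low on every positive-emotion cluster
  act[nonpos, ] <- stats::rnorm(sum(nonpos) * 3L, -0.8, 0.3) *
    (model@clusterActivationSd > 0 | model@clusterBoost > 0)
  tgt <- clips$target_emotion
  ok <- !is.na(tgt)
  act[cbind(which(ok), match(model@clusterAssignment[tgt[ok]], clusterNames()))] <-
    act[cbind(which(ok), match(model@clusterAssignment[tgt[ok]], clusterNames()))] +
    model@clusterBoost

  mu <- matrix(model@baseRating, nClips, length(items),
               dimnames = list(clips$clip_id, items))
  mu[, pos] <- model@baseRating + act %*% t(model@loadings[pos, , drop = FALSE])
  mu[cbind(which(ok), match(tgt[ok], items))] <-
    mu[cbind(which(ok), match(tgt[ok], items))] + model@targetBoost

  structured <- model@clusterActivationSd > 0 || model@clusterBoost > 0 ||
    model@targetBoost > 0
  if ("valence" %in% items) {
    vmu <- c(positive = 5.3, negative = 2.0, neutral = 4.0)[clips$category]
    if (!structured) vmu <- rep(model@baseRating, nClips)
    mu[, "valence"] <- vmu + stats::rnorm(nClips, 0, 0.4 * structured)
  }
  if ("arousal" %in% items) {
    amu <- if (structured)
      4 + 0.7 * act[, "playfulness"] - 0.9 * act[, "harmony"]
    else rep(model@baseRating, nClips)
    mu[, "arousal"] <- amu + stats::rnorm(nClips, 0, 0.5 * structured)
  }
  if ("familiarity" %in% items)
    mu[, "familiarity"] <- (if (structured) 3.5 else model@baseRating) +
      stats::rnorm(nClips, 0, 1.0 * structured)
  if ("liking" %in% items)
    mu[, "liking"] <- (if (structured)
      4.3 + 0.5 * (mu[, "valence"] - 4) else model@baseRating) +
      stats::rnorm(nClips, 0, 0.4 * structured)

  # clip-by-item idiosyncratic component, shared across participants
  mu + matrix(stats::rnorm(length(mu), 0, model@itemNoiseSd), nrow = nClips)
}

#' Generate a synthetic rating table
#'
#' Draws participants x clips x items Likert ratings from the latent model:
#' clip-level cluster activations and target-emotion boosts define the
#' expected ratings (identical for every participant), and independent
#' participant noise is added before round-half-up discretization and
#' clipping to [1, 7]. With zero participant noise all raters agree exactly.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param model a \linkS4class{LatentEmotionModel}.
#' @param seed optional integer; defaults to the design's seed.
#' @return A \linkS4class{RatingTable}.
#' @examples
#' rt <- generateRatings(studyDesign(nParticipants = 4, seed = 7))
#' dim(ratingValues(rt))
#' @export
generateRatings <- function(design, model = latentEmotionModel(), seed = NULL) {
  seed <- seed %||% design@seed
  set.seed(deriveSeed(seed, "ratings"))
  mu <- latentClipMeans(design, model)
  nP <- design@nParticipants
  vals <- array(0L, dim = c(nP, nrow(mu), ncol(mu)),
                dimnames = list(participantIds(design), rownames(mu),
                                colnames(mu)))
  for (p in seq_len(nP)) {
    noise <- matrix(stats::rnorm(length(mu), 0, model@participantNoiseSd),
                    nrow = nrow(mu))
    vals[p, , ] <- likertDiscretize(mu + noise)
  }
  new("RatingTable", values = vals)
}

#' Cross-participant mean ratings
#'
#' @param table a \linkS4class{RatingTable}.
#' @return clips x items matrix of mean ratings.
#' @export
meanRatings <- function(table) {
  apply(ratingValues(table), c(2L, 3L), mean)
}
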