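#' @include AllClasses.R signal-features.R
NULL

#' Correlate clip-level band power with one participant's ratings
#'
#' Pearson correlation, over clips, between baseline-corrected band power
#' and the participant's rating of each item, for every channel x band x
#' item combination. Entries with zero power variance are stored as NA with
#' a warning (and excluded later from averages).
#'
#' @param power a clip-level \linkS4class{BandPowerTensor}.
#' @param ratings clips x items numeric matrix (one participant), or a
#'   \linkS4class{RatingTable} together with \code{participant}.
#' @param participant participant id when \code{ratings} is a RatingTable.
#' @return A \linkS4class{TopographyMap} with \code{level = "participant"}.
#' @export
correlatePowerRatings <- function(power, ratings, participant = NULL) {
  stopifnot(is(power, "BandPowerTensor"), power@level == "clip")
  if (is(ratings, "RatingTable")) {
    if (is.null(participant))
      stop("give a participant id with a RatingTable")
    ratings <- ratingValues(ratings)[participant, , , drop = TRUE]
  }
  cids <- rowInfo(power)$clip_id
  if (!all(cids %in% rownames(ratings)))
    stop("power and ratings are misaligned on clip ids")
  ratings <- ratings[cids, , drop = FALSE]
  if (length(cids) < 3L) stop("need at least 3 clips to correlate")
  pv <- power@values # clips x channels x bands
  d <- dim(pv)
  flat <- matrix(pv, nrow = d[1L]) # clips x (channels*bands)
  constant <- apply(flat, 2L, stats::sd) == 0
  if (any(constant))
    warning(sum(constant), " channel-band series with zero variance; ",
            "correlations set to NA")
  r <- suppressWarnings(stats::cor(flat, ratings))
  r[constant, ] <- NA_real_
  rItems <- apply(ratings, 2L, stats::sd) == 0
  r[, rItems] <- NA_real_
  arr <- array(r, dim = c(d[2L], d[3L], ncol(ratings)),
               dimnames = list(dimnames(pv)[[2L]], dimnames(pv)[[3L]],
                               colnames(ratings)))
  new("TopographyMap", r = arr, nClips = length(cids), nMaps = 1L,
      level = "participant")
}

#' Average correlation topographies across participants
#'
#' Elementwise arithmetic mean of the per-participant correlation maps
#' (plain averaging by default; optional Fisher-z averaging). NA entries are
#' dropped per cell with count tracking.
#'
#' @param maps list of \linkS4class{TopographyMap} objects of equal shape.
#' @param fisherZ average in the Fisher-z domain instead of averaging r.
#' @return A \linkS4class{TopographyMap} with \code{level = "average"}.
#' @export
averageTopography <- function(maps, fisherZ = FALSE) {
  if (!length(maps)) stop("empty list of topographies")
  dims <- lapply(maps, function(m) dim(corrValues(m)))
  if (!all(vapply(dims, identical, TRUE, dims[[1L]])))
    stop("topographies must have identical shapes")
  arrs <- lapply(maps, corrValues)
  if (fisherZ) arrs <- lapply(arrs, atanh)
  stack <- array(unlist(arrs), dim = c(dim(arrs[[1L]]), length(arrs)))
  avg <- apply(stack, 1:3, mean, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  if (fisherZ) avg <- tanh(avg)
  dimnames(avg) <- dimnames(arrs[[1L]])
  new("TopographyMap", r = avg,
      nClips = maps[[1L]]@nClips, nMaps = length(maps), level = "average")
}

#' Sign-recovery score of an estimated topography against the planted truth
#'
#' Fraction of entries with \code{|truth| >= threshold} whose estimated sign
#' matches the planted sign. NA estimates count as misses.
#'
#' @param estimated,truth \linkS4class{TopographyMap} objects of the same
#'   shape (truth typically from \code{\link{plantedTruth}}).
#' @param threshold magnitude below which truth entries are ignored.
#' @return Fraction in [0, 1].
#' @export
recoveryScore <- function(estimated, truth, threshold = 0.1) {
  est <- corrValues(estimated)
  tru <- corrValues(truth)
  if (!identical(dim(est), dim(tru)))
    stop("estimated and truth maps must have the same shape")
  mask <- is.finite(tru) & abs(tru) >= threshold
  if (!any(mask)) stop("no truth entries at or above the threshold")
  hits <- sign(est[mask]) == sign(tru[mask])
  hits[is.na(hits)] <- FALSE
  mean(hits)
}

#' Long-format view of a topography
#'
#' @param map a \linkS4class{TopographyMap}.
#' @return data.frame with channel, band, item, r and n columns.
#' @export
topographyToLong <- function(map) {
  r <- corrValues(map)
  dn <- dimnames(r)
  data.frame(channel = rep(dn[[1L]], times = length(dn[[2L]]) * length(dn[[3L]])),
             band = rep(rep(dn[[2L]], each = length(dn[[1L]])),
                        times = length(dn[[3L]])),
             item = rep(dn[[3L]], each = length(dn[[1L]]) * length(dn[[2L]])),
             r = as.vector(r), n = map@nClips, stringsAsFactors = FALSE)
}
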