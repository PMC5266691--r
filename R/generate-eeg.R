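#' @include design.R signal-features.R
NULL

# Resolve per-band mean-power targets into per-bin targets on the DFT grid
# of an n-sample segment. Bands are processed narrowest first; bins already
# fixed by a narrower band are honoured by adjusting the remaining bins so
# the wider band's MEAN still matches (this resolves the nested
# low-alpha / alpha pair exactly). Bins outside every band get a 1/f
# background; negative solutions are floored at zero. The bin bookkeeping
# depends only on (n, fs, bands) and is cached across segments.
.binGroupCache <- new.env(parent = emptyenv())

binGroups <- function(n, fs, bands, background) {
  key <- paste(n, fs, background, paste(bands$name, bands$f_lo, bands$f_hi,
                                        collapse = ";"), sep = "|")
  hit <- .binGroupCache[[key]]
  if (!is.null(hit)) return(hit)
  half <- n %/% 2L
  freq <- (0:half) * fs / n
  taken <- rep(FALSE, half + 1L)
  ord <- order(bands$f_hi - bands$f_lo)
  groups <- vector("list", nrow(bands))
  for (b in ord) {
    sel <- which(freq >= bands$f_lo[b] & freq <= bands$f_hi[b])
    free <- sel[!taken[sel]]
    groups[[b]] <- list(band = bands$name[b], sel = sel, free = free)
    taken[free] <- TRUE
  }
  bg <- which(!taken & freq >= 0.4)
  bg <- bg[bg > 1L]
  out <- list(groups = groups[ord], bg = bg, bgPower = background / freq[bg],
              nBins = half + 1L)
  .binGroupCache[[key]] <- out
  out
}

# per-bin one-sided power targets, bins x channels
binTargetMatrix <- function(n, fs, powerMatrix, bands, background = 3) {
  gs <- binGroups(n, fs, bands, background)
  nCh <- nrow(powerMatrix)
  tg <- matrix(0, gs$nBins, nCh)
  for (g in gs$groups) {
    if (!length(g$free)) next
    tot <- length(g$sel) * powerMatrix[, g$band]
    fixed <- setdiff(g$sel, g$free)
    rem <- if (length(fixed)) tot - colSums(tg[fixed, , drop = FALSE]) else tot
    tg[g$free, ] <- rep(pmax(rem / length(g$free), 0), each = length(g$free))
  }
  if (length(gs$bg)) tg[gs$bg, ] <- gs$bgPower
  tg
}

# Synthesize one segment (channels x n) whose one-sided periodogram equals
# the requested per-bin power exactly, with independent random phases per
# channel and realization. binPower is bins x channels.
synthesizeSegment <- function(binPower, n) {
  nChannels <- ncol(binPower)
  half <- n %/% 2L
  even <- n %% 2L == 0L
  nInner <- if (even) half - 1L else half
  amp <- binPower
  amp[1L, ] <- n * sqrt(binPower[1L, ])
  if (nInner > 0L)
    amp[2:(nInner + 1L), ] <- n * sqrt(binPower[2:(nInner + 1L), , drop = FALSE] / 2)
  if (even) amp[half + 1L, ] <- n * sqrt(binPower[half + 1L, ])
  X <- matrix(0 + 0i, n, nChannels)
  ph <- matrix(stats::runif(nInner * nChannels, -pi, pi), nInner, nChannels)
  X[2:(nInner + 1L), ] <- amp[2:(nInner + 1L), , drop = FALSE] * exp(1i * ph)
  X[n:(n - nInner + 1L), ] <- Conj(X[2:(nInner + 1L), , drop = FALSE])
  X[1L, ] <- amp[1L, ]
  if (even) X[half + 1L, ] <- amp[half + 1L, ] *
    sign(stats::runif(nChannels) - 0.5)
  t(Re(stats::mvfft(X, inverse = TRUE)) / n)
}

segmentAtPower <- function(n, fs, powerMatrix, bands, background = 3) {
  synthesizeSegment(binTargetMatrix(n, fs, powerMatrix, bands, background), n)
}

#' Generate affect-modulated synthetic EEG sessions
#'
#' For each participant, builds a continuous 32-channel recording containing
#' every clip preceded by a rest gap. Within a clip's final analysis window,
#' the per-band spectral power of channel \code{ch} is set to
#' \code{basePower[ch,b] + sum_i beta[ch,b,i] * z(rating_i) + noise}, where
#' \code{z} standardizes each item's ratings across the clips of that
#' participant; baseline and rest segments carry the unmodulated base power.
#' Band-limited synthesis shapes white noise in the frequency domain with
#' fresh random phases per segment, so the realized rectangular-window
#' periodogram of each whole segment matches its target exactly; a 1/f
#' background fills the out-of-band spectrum. The negative-power floor is 0.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param ratings a \linkS4class{RatingTable} covering the design's clips.
#' @param effects an \linkS4class{EffectMap}.
#' @param participants participant ids (or indices) to generate; default all.
#' @param seed optional integer; defaults to the design's seed. Sessions are
#'   reproducible per participant regardless of which subset is generated.
#' @return A named list of \linkS4class{EEGSession} objects.
#' @export
generateEEG <- function(design, ratings, effects = effectMap("planted"),
                        participants = NULL, seed = NULL) {
  seed <- seed %||% design@seed
  fs <- design@samplingRate
  clips <- design@clips
  if (!all(clips$clip_id %in% clipIds(ratings)))
    stop("ratings do not cover all clips in the design")
  if (any(clips$duration_s < design@clipWindow))
    stop("clip duration below the analysis window")
  pids <- participantIds(design)
  participants <- participants %||% pids
  if (is.numeric(participants)) participants <- pids[participants]
  items <- dimnames(effects@beta)[[3L]]
  chs <- dimnames(effects@beta)[[1L]]
  stopifnot(identical(chs, design@channels))
  bands <- effects@bands
  nW <- round(design@clipWindow * fs)
  nB <- round(design@baseline * fs)
  nGapExtra <- round((design@interClipGap - design@baseline) * fs)

  sessions <- list()
  for (pid in participants) {
    set.seed(deriveSeed(seed, "eeg", pid))
    rmat <- ratingValues(ratings)[pid, clips$clip_id, items, drop = TRUE]
    z <- apply(rmat, 2L, zScore) # clips x items
    segs <- list(); k <- 0L
    events <- data.frame(clip_id = character(), onset_sample = integer(),
                         offset_sample = integer(), stringsAsFactors = FALSE)
    cursor <- 0L
    addSeg <- function(m) { k <<- k + 1L; segs[[k]] <<- m; cursor <<- cursor + ncol(m) }
    for (ci in seq_len(nrow(clips))) {
      if (nGapExtra > 0L)
        addSeg(segmentAtPower(nGapExtra, fs, effects@basePower, bands))
      addSeg(segmentAtPower(nB, fs, effects@basePower, bands))
      onset <- cursor + 1L
      nExtra <- round(clips$duration_s[ci] * fs) - nW
      if (nExtra > 0L)
        addSeg(segmentAtPower(nExtra, fs, effects@basePower, bands))
      target <- effects@basePower +
        matrix(tensorContract(effects@beta, z[ci, ]), nrow = length(chs)) +
        matrix(stats::rnorm(length(effects@basePower), 0,
                            effects@powerNoiseSd),
               nrow = length(chs))
      target[target < 0] <- 0
      dimnames(target) <- dimnames(effects@basePower)
      addSeg(segmentAtPower(nW, fs, target, bands))
      events <- rbind(events, data.frame(clip_id = clips$clip_id[ci],
                                         onset_sample = onset,
                                         offset_sample = cursor,
                                         stringsAsFactors = FALSE))
    }
    sig <- do.call(cbind, segs)
    rownames(sig) <- chs
    sessions[[pid]] <- new("EEGSession", signals = sig, samplingRate = fs,
                           channelLabels = chs, events = events,
                           participantId = pid)
  }
  sessions
}

# contract a channels x bands x items array with an item vector
tensorContract <- function(beta, zItems) {
  d <- dim(beta)
  matrix(beta, ncol = d[3L]) %*% zItems
}

#' Export the planted effect signs as a truth topography
#'
#' @param effects an \linkS4class{EffectMap}.
#' @return A \linkS4class{TopographyMap} with \code{level = "truth"} whose
#'   entries are the planted beta coefficients (compare signs, or threshold
#'   on magnitude, against estimated maps).
#' @export
plantedTruth <- function(effects) {
  new("TopographyMap", r = effects@beta, nClips = 0L, nMaps = 1L,
      level = "truth")
}
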