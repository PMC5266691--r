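#' @include AllClasses.R design.R
NULL

# One-sided rectangular-window periodogram, per-bin power convention:
# the one-sided bin powers sum to mean(x^2) (Parseval). Input channels x
# samples; returns list(freq, power = channels x bins).
periodogramPower <- function(segment, fs) {
  if (is.null(dim(segment))) segment <- matrix(segment, nrow = 1L)
  n <- ncol(segment)
  X <- t(stats::mvfft(t(segment)))
  half <- n %/% 2L
  p <- (Mod(X)^2) / n^2
  pow <- p[, seq_len(half + 1L), drop = FALSE]
  if (n %% 2L == 0L) {
    if (half > 1L) pow[, 2:half] <- 2 * pow[, 2:half]
  } else {
    pow[, 2:(half + 1L)] <- 2 * pow[, 2:(half + 1L)]
  }
  list(freq = (0:half) * fs / n, power = pow)
}

#' Band-averaged spectral power of a multichannel segment
#'
#' Computes the one-sided rectangular-window periodogram of each channel
#' (single FFT over the whole segment, no taper) and averages the per-bin
#' power over the DFT bins whose frequency lies in \code{[f_lo, f_hi]}
#' (inclusive edges) for each band.
#'
#' @param segment channels x samples numeric matrix (or a vector for one
#'   channel), microvolts.
#' @param fs sampling rate, Hz.
#' @param bands band definition data.frame (\code{name}, \code{f_lo},
#'   \code{f_hi}); default \code{\link{defaultBands}}.
#' @return channels x bands matrix of mean per-bin power (uV^2).
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 1 - 1/250, by = 1/250))
#' bandPower(x, 250)["1", c("alpha", "theta")]
#' @export
bandPower <- function(segment, fs, bands = defaultBands()) {
  if (is.null(dim(segment))) segment <- matrix(segment, nrow = 1L)
  if (ncol(segment) < fs) stop("segment must be at least 1 s long")
  pg <- periodogramPower(segment, fs)
  out <- matrix(NA_real_, nrow(segment), nrow(bands),
                dimnames = list(rownames(segment) %||% seq_len(nrow(segment)),
                                bands$name))
  for (b in seq_len(nrow(bands))) {
    sel <- pg$freq >= bands$f_lo[b] & pg$freq <= bands$f_hi[b]
    if (!any(sel))
      stop("band '", bands$name[b], "' contains no DFT bins at this resolution")
    out[, b] <- rowMeans(pg$power[, sel, drop = FALSE])
  }
  out
}

#' Subtract baseline band power from clip band power
#'
#' Elementwise subtraction in linear power units; results may be negative.
#'
#' @param clipPower,baselinePower channels x bands matrices of equal shape.
#' @return channels x bands matrix \code{clipPower - baselinePower}.
#' @export
baselineCorrect <- function(clipPower, baselinePower) {
  if (!identical(dim(clipPower), dim(baselinePower)))
    stop("clip and baseline power matrices must have the same shape")
  clipPower - baselinePower
}

#' Zero-phase notch + bandpass preprocessing
#'
#' Applies a 50 Hz biquad notch (Q = 30) and a Butterworth bandpass
#' (0.05-50 Hz by default, 2nd order each direction), both forward-backward
#' (\code{signal::filtfilt}) so the output is zero-phase. An optional
#' channels x samples artifact mask can be multiplied in, as a hook for an
#' externally computed artifact (e.g. ICA) rejection; no artifact detection
#' is performed here.
#'
#' @param session an \linkS4class{EEGSession}.
#' @param notchHz powerline frequency to notch out (NULL to skip).
#' @param band length-2 passband in Hz (NULL to skip).
#' @param notchQ quality factor of the notch.
#' @param artifactMask optional numeric matrix (channels x samples) applied
#'   multiplicatively after filtering.
#' @return The filtered \linkS4class{EEGSession} (same shape, labels, events).
#' @export
preprocessSession <- function(session, notchHz = 50, band = c(0.05, 50),
                              notchQ = 30, artifactMask = NULL) {
  fs <- session@samplingRate
  x <- session@signals
  if (!is.null(band)) {
    if (any(band >= fs / 2)) stop("passband must lie below the Nyquist frequency")
    if (!is.null(notchHz) && notchHz >= fs / 2)
      stop("notch frequency must lie below the Nyquist frequency")
  }
  if (!is.null(notchHz)) {
    w0 <- 2 * pi * notchHz / fs
    alpha <- sin(w0) / (2 * notchQ)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    b <- b / a[1L]; a <- a / a[1L]
    for (ch in seq_len(nrow(x)))
      x[ch, ] <- signal::filtfilt(filt = b, a = a, x = x[ch, ])
  }
  if (!is.null(band)) {
    bp <- signal::butter(2, band / (fs / 2), type = "pass")
    for (ch in seq_len(nrow(x)))
      x[ch, ] <- signal::filtfilt(bp, x[ch, ])
  }
  if (!is.null(artifactMask)) x <- x * artifactMask
  initialize(session, signals = x)
}

#' Extract per-clip analysis and baseline windows
#'
#' For each clip event, takes the final \code{clipWindow} seconds before the
#' clip offset and the \code{baseline} seconds immediately before the onset.
#' Clips with insufficient signal are skipped with a warning.
#'
#' @param session an \linkS4class{EEGSession}.
#' @param clipWindow analysis window length, seconds.
#' @param baseline baseline length, seconds.
#' @return Named list (by clip id) of lists with elements \code{clip} and
#'   \code{baseline}, each a channels x samples matrix.
#' @export
extractWindows <- function(session, clipWindow = 30, baseline = 5) {
  fs <- session@samplingRate
  nw <- round(clipWindow * fs)
  nb <- round(baseline * fs)
  out <- list()
  for (i in seq_len(nrow(session@events))) {
    ev <- session@events[i, ]
    if (ev$offset_sample - ev$onset_sample + 1L < nw) {
      warning("clip ", ev$clip_id, " shorter than the analysis window; skipped")
      next
    }
    if (ev$onset_sample - nb < 1L) {
      warning("clip ", ev$clip_id, " lacks pre-onset baseline signal; skipped")
      next
    }
    out[[ev$clip_id]] <- list(
      clip = session@signals[, (ev$offset_sample - nw + 1L):ev$offset_sample,
                             drop = FALSE],
      baseline = session@signals[, (ev$onset_sample - nb):(ev$onset_sample - 1L),
                                 drop = FALSE])
  }
  out
}

#' Clip-level baseline-corrected band-power features
#'
#' One spectral estimate per clip: band power over the whole clip-final
#' window, minus band power over the pre-onset baseline.
#'
#' @param session an \linkS4class{EEGSession}.
#' @param bands band definition table.
#' @param clipWindow,baseline window lengths in seconds.
#' @param clipIds optional subset of clip ids to keep (default all events).
#' @return A clip-level \linkS4class{BandPowerTensor}
#'   (clips x channels x bands).
#' @export
clipFeatures <- function(session, bands = defaultBands(), clipWindow = 30,
                         baseline = 5, clipIds = NULL) {
  fs <- session@samplingRate
  wins <- extractWindows(session, clipWindow, baseline)
  if (!is.null(clipIds)) wins <- wins[names(wins) %in% clipIds]
  if (!length(wins)) stop("no usable clips")
  vals <- array(NA_real_, dim = c(length(wins), length(session@channelLabels),
                                  nrow(bands)),
                dimnames = list(names(wins), session@channelLabels, bands$name))
  for (i in seq_along(wins)) {
    vals[i, , ] <- baselineCorrect(bandPower(wins[[i]]$clip, fs, bands),
                                   bandPower(wins[[i]]$baseline, fs, bands))
  }
  new("BandPowerTensor", values = vals,
      rowData = data.frame(clip_id = names(wins), stringsAsFactors = FALSE),
      bands = bands, level = "clip", baselineCorrected = TRUE)
}

#' Epoch-level baseline-corrected band-power features
#'
#' Cuts each clip window into non-overlapping 1-s epochs and computes the
#' band power of every epoch, corrected by subtracting the band power of the
#' clip's single pre-onset baseline. With the default design (30 positive
#' clips, 30-s windows) this yields 900 epochs of 32 x 5 = 160 features per
#' participant.
#'
#' @param session an \linkS4class{EEGSession}.
#' @param bands band definition table.
#' @param clipWindow,baseline window lengths in seconds.
#' @param epochLength epoch length in seconds.
#' @param clipIds optional subset of clip ids (e.g. the positive clips).
#' @return An epoch-level \linkS4class{BandPowerTensor} whose
#'   \code{rowInfo()} carries \code{clip_id} and \code{epoch}.
#' @export
epochFeatures <- function(session, bands = defaultBands(), clipWindow = 30,
                          baseline = 5, epochLength = 1, clipIds = NULL) {
  fs <- session@samplingRate
  ne <- floor(clipWindow / epochLength)
  nsE <- round(epochLength * fs)
  wins <- extractWindows(session, clipWindow, baseline)
  if (!is.null(clipIds)) wins <- wins[names(wins) %in% clipIds]
  if (!length(wins)) stop("no usable clips")
  nRows <- length(wins) * ne
  nCh <- length(session@channelLabels)
  vals <- array(NA_real_, dim = c(nRows, nCh, nrow(bands)),
                dimnames = list(NULL, session@channelLabels, bands$name))
  rowClip <- character(nRows); rowEpoch <- integer(nRows)
  freq <- (0:(nsE %/% 2L)) * fs / nsE
  bandSel <- lapply(seq_len(nrow(bands)), function(b) {
    sel <- freq >= bands$f_lo[b] & freq <= bands$f_hi[b]
    if (!any(sel))
      stop("band '", bands$name[b], "' contains no DFT bins at this resolution")
    sel
  })
  r <- 0L
  for (i in seq_along(wins)) {
    basePow <- bandPower(wins[[i]]$baseline, fs, bands)
    # one FFT over all (epoch, channel) series of the clip at once
    segs <- array(t(wins[[i]]$clip[, seq_len(ne * nsE), drop = FALSE]),
                  dim = c(nsE, ne * nCh))
    pg <- periodogramPower(t(segs), fs)
    rows <- r + seq_len(ne)
    for (b in seq_len(nrow(bands)))
      vals[rows, , b] <- matrix(rowMeans(pg$power[, bandSel[[b]],
                                                  drop = FALSE]),
                                ne, nCh) - rep(basePow[, b], each = ne)
    rowClip[rows] <- names(wins)[i]
    rowEpoch[rows] <- seq_len(ne)
    r <- r + ne
  }
  new("BandPowerTensor", values = vals,
      rowData = data.frame(clip_id = rowClip, epoch = rowEpoch,
                           stringsAsFactors = FALSE),
      bands = bands, level = "epoch", baselineCorrected = TRUE)
}
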