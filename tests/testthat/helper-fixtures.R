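# Shared fixtures, built in code. Heavier objects are memoised so several
# test files can reuse one generation pass.

fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixtureCache[[key]])) fixtureCache[[key]] <- force(expr)
  fixtureCache[[key]]
}

# default-structure design with short clips (keeps EEG synthesis light)
shortClipDesign <- function(nParticipants = 2L, seed = 101L) {
  studyDesign(nParticipants = nParticipants,
              clips = defaultClips(seed = seed, durationRange = c(30, 34)),
              seed = seed)
}

smallStudy <- function() {
  cached("smallStudy", {
    design <- shortClipDesign(nParticipants = 2L, seed = 101L)
    ratings <- generateRatings(design)
    effects <- effectMap("planted")
    session <- generateEEG(design, ratings, effects,
                           participants = "P01")[[1L]]
    list(design = design, ratings = ratings, effects = effects,
         session = session)
  })
}

smallEpochTensor <- function() {
  cached("smallEpochTensor", {
    st <- smallStudy()
    pos <- st$design@clips$clip_id[st$design@clips$category == "positive"]
    epochFeatures(st$session, bands = st$effects@bands, clipWindow = 30,
                  baseline = 5, clipIds = pos)
  })
}

# brute-force DFT band-power oracle, written independently of bandPower:
# explicit DFT sums, one-sided per-bin power, mean over in-band bins
oracleBandPower <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  half <- n %/% 2L
  freqs <- (0:half) * fs / n
  p <- numeric(half + 1L)
  for (k in 0:half) {
    re <- sum(x * cos(2 * pi * k * (0:(n - 1)) / n))
    im <- -sum(x * sin(2 * pi * k * (0:(n - 1)) / n))
    pk <- (re^2 + im^2) / n^2
    if (k > 0 && !(n %% 2 == 0 && k == half)) pk <- 2 * pk
    p[k + 1L] <- pk
  }
  sel <- freqs >= f_lo & freqs <= f_hi
  mean(p[sel])
}

# toy rating table from a clips x participants matrix, one item
ratingTableFromMatrix <- function(m, item = "joy") {
  nP <- ncol(m); nC <- nrow(m)
  v <- array(NA_integer_, dim = c(nP, nC, 1L),
             dimnames = list(sprintf("P%02d", seq_len(nP)),
                             sprintf("clip_%d", seq_len(nC)), item))
  for (p in seq_len(nP)) v[p, , 1L] <- as.integer(m[, p])
  new("RatingTable", values = v)
}

# rating table with exact item columns (same for every participant)
ratingTableFromItems <- function(itemMatrix, nParticipants = 2L) {
  v <- array(NA_integer_,
             dim = c(nParticipants, nrow(itemMatrix), ncol(itemMatrix)),
             dimnames = list(sprintf("P%02d", seq_len(nParticipants)),
                             rownames(itemMatrix) %||%
                               sprintf("clip_%d", seq_len(nrow(itemMatrix))),
                             colnames(itemMatrix)))
  for (p in seq_len(nParticipants)) v[p, , ] <- as.integer(itemMatrix)
  new("RatingTable", values = v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal synthetic EEG session wrapper for filter/window tests
sessionFromSignal <- function(signals, fs = 250, events = NULL) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1L)
  labels <- rownames(signals) %||% sprintf("ch%d", seq_len(nrow(signals)))
  rownames(signals) <- labels
  if (is.null(events))
    events <- data.frame(clip_id = "clip_1",
                         onset_sample = as.integer(5 * fs + 1L),
                         offset_sample = ncol(signals))
  new("EEGSession", signals = signals, samplingRate = fs,
      channelLabels = labels, events = events, participantId = "P01")
}
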