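# Spectral feature extraction: periodogram convention locked by Parseval,
# band power checked against an independent brute-force DFT oracle, filters
# checked on pure tones, and window/epoch arithmetic checked by counting.

test_that("periodogram bins sum to the mean squared signal (Parseval)", {
  set.seed(5)
  for (n in c(250L, 251L, 1250L)) {
    x <- matrix(rnorm(2L * n), nrow = 2L)
    pg <- emospect:::periodogramPower(x, 250)
    expect_equal(rowSums(pg$power), rowMeans(x^2), tolerance = 1e-6)
  }
})

test_that("band power matches the brute-force DFT oracle on random segments", {
  set.seed(7)
  bands <- defaultBands()
  worst <- 0
  for (i in 1:12) {
    x <- rnorm(250)
    bp <- bandPower(x, 250, bands)
    for (b in sample(nrow(bands), 2L)) {
      oracle <- oracleBandPower(x, 250, bands$f_lo[b], bands$f_hi[b])
      worst <- max(worst, abs(bp[1L, b] - oracle) / oracle)
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("a pure 10 Hz tone lands entirely in the alpha bands", {
  fs <- 250
  x <- sin(2 * pi * 10 * seq(0, 1 - 1 / fs, by = 1 / fs))
  bp <- bandPower(x, fs)[1L, ]
  expect_gt(bp[["alpha"]], 0)
  expect_gt(bp[["low_alpha"]], 0)
  expect_equal(bp[["theta"]], 0, tolerance = 1e-12)
  expect_equal(bp[["beta"]], 0, tolerance = 1e-12)
  expect_equal(bp[["gamma"]], 0, tolerance = 1e-12)
  # all tone power (amplitude^2 / 2) sits in the single 10 Hz bin
  expect_equal(bp[["low_alpha"]], 0.5 / 3, tolerance = 1e-9)
  expect_equal(bp[["alpha"]], 0.5 / 6, tolerance = 1e-9)
  # oracle agreement on the tone as well
  expect_equal(bp[["alpha"]], oracleBandPower(x, fs, 8, 13), tolerance = 1e-9)
})

test_that("zero and white-noise segments give flat band structure", {
  expect_true(all(bandPower(matrix(0, 2, 500), 250) == 0))
  set.seed(11)
  acc <- matrix(0, 120, 5)
  for (i in 1:120) acc[i, ] <- bandPower(rnorm(500), 250)[1L, ]
  m <- colMeans(acc)
  expect_lt(diff(range(m)) / mean(m), 0.1)
})

test_that("band definitions outside the resolution or Nyquist fail loudly", {
  bad <- data.frame(name = "narrow", f_lo = 10.2, f_hi = 10.4)
  expect_error(bandPower(rnorm(250), 250, bad), "no DFT bins")
  expect_error(bandPower(rnorm(100), 250), "1 s")
})

test_that("baseline correction is elementwise subtraction", {
  a <- matrix(c(2, 5), 1); b <- matrix(c(1, 7), 1)
  expect_equal(baselineCorrect(a, b), matrix(c(1, -2), 1))
  expect_true(all(baselineCorrect(a, a) == 0))
  expect_equal(baselineCorrect(a, matrix(0, 1, 2)), a)
  expect_error(baselineCorrect(a, matrix(0, 2, 2)), "shape")
})

test_that("preprocessing attenuates 50 Hz by 30 dB and passes 10 Hz", {
  fs <- 250
  tt <- seq(0, 8 - 1 / fs, by = 1 / fs)
  s50 <- sessionFromSignal(sin(2 * pi * 50 * tt), fs)
  s10 <- sessionFromSignal(sin(2 * pi * 10 * tt), fs)
  mid <- 500:1500 # avoid filter edge transients
  rms <- function(x) sqrt(mean(x^2))
  out50 <- preprocessSession(s50)
  expect_lt(rms(signalMatrix(out50)[1, mid]) / rms(signalMatrix(s50)[1, mid]),
            0.0316) # >= 30 dB
  out10 <- preprocessSession(s10)
  expect_equal(rms(signalMatrix(out10)[1, mid]) /
                 rms(signalMatrix(s10)[1, mid]), 1, tolerance = 0.1)
  z <- sessionFromSignal(rep(0, length(tt)), fs)
  expect_true(all(abs(signalMatrix(preprocessSession(z))) < 1e-10))
  expect_error(preprocessSession(s10, band = c(0.05, 200)), "Nyquist")
})

test_that("artifact-mask hook multiplies in externally supplied masks", {
  fs <- 250
  x <- matrix(rnorm(2 * fs * 6), nrow = 2)
  s <- sessionFromSignal(x, fs)
  mask <- matrix(1, 2, ncol(x)); mask[1, 1:100] <- 0
  out <- preprocessSession(s, notchHz = NULL, band = NULL,
                           artifactMask = mask)
  expect_true(all(signalMatrix(out)[1, 1:100] == 0))
  expect_equal(signalMatrix(out)[2, ], x[2, ])
})

test_that("window extraction takes the clip-final window and pre-onset baseline", {
  fs <- 250
  n <- 140 * fs
  x <- matrix(seq_len(n), nrow = 1) # sample index as signal value
  ev <- data.frame(clip_id = "long_clip",
                   onset_sample = 2000L,
                   offset_sample = 2000L + 129L * fs - 1L) # a 129-s clip
  s <- sessionFromSignal(x, fs, ev)
  w <- extractWindows(s, clipWindow = 30, baseline = 5)
  expect_equal(ncol(w$long_clip$clip), 30L * fs)
  expect_equal(ncol(w$long_clip$baseline), 5L * fs)
  # clip window covers exactly the last 30 s before offset
  expect_equal(w$long_clip$clip[1, ],
               as.numeric((ev$offset_sample - 30L * fs + 1L):ev$offset_sample))
  # baseline covers the 5 s immediately before onset
  expect_equal(w$long_clip$baseline[1, ],
               as.numeric((ev$onset_sample - 5L * fs):(ev$onset_sample - 1L)))
})

test_that("a clip exactly as long as the window is used whole", {
  fs <- 250
  ev <- data.frame(clip_id = "exact", onset_sample = 1251L,
                   offset_sample = 1250L + 30L * fs)
  s <- sessionFromSignal(matrix(rnorm(1250 + 30 * fs), 1), fs, ev)
  w <- extractWindows(s, 30, 5)
  expect_equal(w$exact$clip[1, ],
               signalMatrix(s)[1, ev$onset_sample:ev$offset_sample])
})

test_that("clips with insufficient signal are skipped with a warning", {
  fs <- 250
  ev <- data.frame(clip_id = c("short", "no_baseline", "ok"),
                   onset_sample = c(2000L, 100L, 10000L),
                   offset_sample = c(2000L + 10L * fs, 100L + 31L * fs,
                                     10000L + 30L * fs))
  s <- sessionFromSignal(matrix(rnorm(10000 + 31 * fs), 1), fs, ev)
  expect_warning(expect_warning(w <- extractWindows(s, 30, 5),
                                "shorter"), "baseline")
  expect_named(w, "ok")
})

test_that("epoch features count rows as clips x floor(window / epoch)", {
  st <- smallStudy()
  pos <- st$design@clips$clip_id[st$design@clips$category == "positive"]
  # one clip -> 30 rows of 32 x 5
  one <- epochFeatures(st$session, clipIds = pos[1L])
  expect_equal(dim(one@values), c(30L, 32L, 5L))
  expect_equal(rowInfo(one)$epoch, 1:30)
  ep <- smallEpochTensor()
  expect_equal(dim(ep@values), c(900L, 32L, 5L))
  expect_equal(ncol(featureMatrix(ep)), 160L)
  # clip-level variant covers all 37 clips
  cf <- clipFeatures(st$session)
  expect_equal(dim(cf@values)[1L], 37L)
  expect_true(cf@baselineCorrected)
})

test_that("epoch features equal the naive per-epoch computation", {
  st <- smallStudy()
  pos <- st$design@clips$clip_id[st$design@clips$category == "positive"]
  ep <- epochFeatures(st$session, clipIds = pos[3L])
  w <- extractWindows(st$session, 30, 5)[[pos[3L]]]
  base <- bandPower(w$baseline, 250)
  for (e in c(1L, 17L)) {
    naive <- bandPower(w$clip[, ((e - 1) * 250 + 1):(e * 250)], 250) - base
    expect_equal(ep@values[e, , ], naive, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})
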