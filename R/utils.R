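#' @keywords internal
#' @noRd
NULL

# Deterministic sub-seed derivation: one study seed drives every random
# stage; per-stage/per-participant streams are derived by hashing string
# tokens so generation order never matters. Kept below 2^31 - 1.
deriveSeed <- function(seed, ...) {
  tokens <- unlist(lapply(list(...), as.character))
  h <- as.double(seed) %% 2147483647
  for (tok in tokens) {
    for (code in utf8ToInt(tok)) {
      h <- (h * 69069 + code) %% 2147483647
    }
  }
  as.integer(h)
}

# round-half-up then clamp to the Likert range
likertDiscretize <- function(x, lo = 1L, hi = 7L) {
  v <- floor(x + 0.5)
  v[v < lo] <- lo
  v[v > hi] <- hi
  storage.mode(v) <- "integer"
  v
}

# z-score a vector; zero-variance input maps to zeros (flagged by caller)
zScore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
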