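#' @include AllClasses.R design.R
NULL

#' Write / read a rating table as long-format CSV
#'
#' Columns \code{participant, clip_id, item, rating}. Reading validates the
#' Likert range and completeness (every participant x clip x item cell
#' present exactly once) and reports offending rows or cells.
#'
#' @param table a \linkS4class{RatingTable}.
#' @param path CSV file path.
#' @return \code{writeRatings} the path invisibly; \code{readRatings} a
#'   \linkS4class{RatingTable}.
#' @export
writeRatings <- function(table, path) {
  v <- ratingValues(table)
  dn <- dimnames(v)
  df <- data.frame(
    participant = rep(dn[[1L]], times = length(dn[[2L]]) * length(dn[[3L]])),
    clip_id = rep(rep(dn[[2L]], each = length(dn[[1L]])),
                  times = length(dn[[3L]])),
    item = rep(dn[[3L]], each = length(dn[[1L]]) * length(dn[[2L]])),
    rating = as.vector(v), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRatings
#' @export
readRatings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "clip_id", "item", "rating")
  if (!all(need %in% names(df)))
    stop("ratings CSV needs columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(df$rating) | df$rating < 1 | df$rating > 7 |
                 df$rating != round(df$rating))
  if (length(bad))
    stop("invalid rating(s) at row(s) ", paste(utils::head(bad, 5L) + 1L,
                                               collapse = ", "),
         " (values must be integers in [1, 7])")
  ps <- unique(df$participant); cs <- unique(df$clip_id); is <- unique(df$item)
  v <- array(NA_integer_, dim = c(length(ps), length(cs), length(is)),
             dimnames = list(ps, cs, is))
  v[cbind(match(df$participant, ps), match(df$clip_id, cs),
          match(df$item, is))] <- as.integer(df$rating)
  if (anyNA(v)) {
    miss <- which(is.na(v), arr.ind = TRUE)[1L, ]
    stop("incomplete rating table: missing cell (participant=", ps[miss[1L]],
         ", clip=", cs[miss[2L]], ", item=", is[miss[3L]], ")")
  }
  new("RatingTable", values = v)
}

#' Write / read an EEG session as delimited matrix plus JSON sidecar
#'
#' The signal matrix goes to a TSV (one column per channel, full double
#' precision) and the sampling rate, channel labels, participant id and
#' clip events to a JSON sidecar named \code{<path>.json}. The round trip
#' preserves samples to the printed precision (~1e-15 relative) and events
#' exactly.
#'
#' @param session an \linkS4class{EEGSession}.
#' @param path TSV file path.
#' @return \code{writeEEGSession} the path invisibly; \code{readEEGSession}
#'   an \linkS4class{EEGSession}.
#' @export
writeEEGSession <- function(session, path) {
  m <- t(signalMatrix(session))
  colnames(m) <- channelNames(session)
  data.table::fwrite(as.data.frame(m), path, sep = "\t")
  meta <- list(sampling_rate = samplingRate(session),
               channels = channelNames(session),
               participant = session@participantId,
               events = sessionEvents(session))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeEEGSession
#' @export
readEEGSession <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing events sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  m <- as.matrix(data.table::fread(path, sep = "\t"))
  if (!identical(colnames(m), as.character(meta$channels)))
    stop("channel labels in ", path, " disagree with the sidecar")
  ev <- as.data.frame(meta$events)
  ev$onset_sample <- as.integer(ev$onset_sample)
  ev$offset_sample <- as.integer(ev$offset_sample)
  new("EEGSession", signals = t(m), samplingRate = meta$sampling_rate,
      channelLabels = as.character(meta$channels), events = ev,
      participantId = as.character(meta$participant))
}

#' Write a band-power tensor as long-format CSV
#'
#' Columns \code{clip_id, epoch (epoch level only), channel, band, power}.
#'
#' @param tensor a \linkS4class{BandPowerTensor}.
#' @param path CSV path.
#' @param participant optional participant id column.
#' @export
writeBandPower <- function(tensor, path, participant = NULL) {
  v <- tensor@values
  dn <- dimnames(v)
  n <- dim(v)
  ri <- rowInfo(tensor)
  df <- data.frame(
    clip_id = rep(ri$clip_id, times = n[2L] * n[3L]),
    channel = rep(rep(dn[[2L]], each = n[1L]), times = n[3L]),
    band = rep(dn[[3L]], each = n[1L] * n[2L]),
    power = as.vector(v), stringsAsFactors = FALSE)
  if (tensor@level == "epoch")
    df <- cbind(df[1L], epoch = rep(ri$epoch, times = n[2L] * n[3L]),
                df[-1L])
  if (!is.null(participant)) df <- cbind(participant = participant, df)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a long-format band-power CSV back into a tensor
#'
#' @param path CSV path written by \code{\link{writeBandPower}}.
#' @param bands band definition table (metadata only).
#' @return A \linkS4class{BandPowerTensor}.
#' @export
readBandPower <- function(path, bands = defaultBands()) {
  df <- as.data.frame(data.table::fread(path))
  hasEpoch <- "epoch" %in% names(df)
  key <- if (hasEpoch) paste(df$clip_id, df$epoch) else df$clip_id
  rows <- unique(key)
  chs <- unique(df$channel); bds <- unique(df$band)
  v <- array(NA_real_, dim = c(length(rows), length(chs), length(bds)),
             dimnames = list(NULL, chs, bds))
  v[cbind(match(key, rows), match(df$channel, chs), match(df$band, bds))] <-
    df$power
  first <- !duplicated(key)
  rowData <- data.frame(clip_id = df$clip_id[first],
                        stringsAsFactors = FALSE)
  if (hasEpoch) rowData$epoch <- as.integer(df$epoch[first])
  new("BandPowerTensor", values = v, rowData = rowData,
      bands = bands[match(bds, bands$name), , drop = FALSE],
      level = if (hasEpoch) "epoch" else "clip", baselineCorrected = TRUE)
}

#' Read a run configuration from YAML or JSON
#'
#' Builds the study design, latent rating model and effect map from a
#' configuration file. Unknown top-level keys raise an error, as do missing
#' required keys; every parameter has the package default.
#'
#' @param path a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return List with elements \code{design} (\linkS4class{StudyDesign}),
#'   \code{model} (\linkS4class{LatentEmotionModel}), \code{effects}
#'   (\linkS4class{EffectMap}), \code{protocols}, \code{folds}, \code{seed}.
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("design", "model", "effects", "protocols", "folds", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  if (is.null(cfg$seed)) stop("config is missing required key 'seed'")
  seed <- as.integer(cfg$seed)
  d <- cfg$design %||% list()
  okD <- c("n_participants", "clip_window_s", "baseline_s", "sampling_rate",
           "inter_clip_gap_s", "clip_duration_range")
  extra <- setdiff(names(d), okD)
  if (length(extra)) stop("unknown design key(s): ", paste(extra, collapse = ", "))
  rng <- d$clip_duration_range %||% c(30, 129)
  design <- studyDesign(
    nParticipants = d$n_participants %||% 20L,
    clips = defaultClips(seed = seed, durationRange = rng),
    samplingRate = d$sampling_rate %||% 250,
    clipWindow = d$clip_window_s %||% 30,
    baseline = d$baseline_s %||% 5,
    interClipGap = d$inter_clip_gap_s %||% 7,
    seed = seed)
  m <- cfg$model %||% list()
  okM <- c("participant_noise_sd", "item_noise_sd", "target_boost",
           "cluster_activation_sd", "cluster_boost", "base_rating", "null")
  extra <- setdiff(names(m), okM)
  if (length(extra)) stop("unknown model key(s): ", paste(extra, collapse = ", "))
  model <- if (isTRUE(m$null)) nullLatentEmotionModel(
    participantNoiseSd = m$participant_noise_sd %||% 0.8)
  else latentEmotionModel(
    participantNoiseSd = m$participant_noise_sd %||% 0.8,
    itemNoiseSd = m$item_noise_sd %||% 0.3,
    targetBoost = m$target_boost %||% 1.5,
    clusterActivationSd = m$cluster_activation_sd %||% 0.8,
    clusterBoost = m$cluster_boost %||% 1.2,
    baseRating = m$base_rating %||% 2.5)
  e <- cfg$effects %||% list()
  okE <- c("preset", "power_noise_sd")
  extra <- setdiff(names(e), okE)
  if (length(extra)) stop("unknown effects key(s): ", paste(extra, collapse = ", "))
  effects <- effectMap(e$preset %||% "planted",
                       powerNoiseSd = e$power_noise_sd %||% 1.0)
  pr <- cfg$protocols %||% list(items = defaultItems(),
                                clusters = clusterNames(),
                                pairwise = utils::combn(clusterNames(), 2L,
                                                        simplify = FALSE))
  if (!is.null(pr$pairwise) && !is.list(pr$pairwise))
    pr$pairwise <- apply(matrix(pr$pairwise, ncol = 2L, byrow = TRUE), 1L,
                         identity, simplify = FALSE)
  list(design = design, model = model, effects = effects,
       protocols = pr, folds = as.integer(cfg$folds %||% 10L), seed = seed)
}

# config fingerprint recorded in every output manifest
configHash <- function(cfg) {
  s <- jsonlite::toJSON(list(n = cfg$design@nParticipants,
                             seed = cfg$seed,
                             folds = cfg$folds,
                             protocols = cfg$protocols),
                        auto_unbox = TRUE)
  # small stable polynomial hash over the serialized config
  h <- 0
  for (code in utf8ToInt(as.character(s)))
    h <- (h * 131 + code) %% 2147483647
  sprintf("%08x", as.integer(h))
}
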