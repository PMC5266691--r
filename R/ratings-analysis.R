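#' @include AllClasses.R design.R generate-ratings.R
NULL

#' Intraclass correlation of an item's ratings across participants
#'
#' Treats clips as targets and participants as raters and computes the ICC
#' from the two-way mean squares of the clips x participants matrix. The
#' default variant is consistency, average-measures (the ICC(2,k)/ICC(C,k)
#' family): \code{(MSR - MSE) / MSR}, where MSR is the between-clip and MSE
#' the residual mean square. Absolute-agreement and single-measure variants
#' are selectable.
#'
#' @param table a \linkS4class{RatingTable}.
#' @param item item name (or index).
#' @param type \code{"consistency"} or \code{"agreement"}.
#' @param unit \code{"average"} (reliability of the mean over raters) or
#'   \code{"single"}.
#' @return The ICC (<= 1), or \code{NA} with a warning when the between-clip
#'   variance is zero (undefined).
#' @examples
#' rt <- generateRatings(studyDesign(nParticipants = 5, seed = 3))
#' icc(rt, "joy")
#' @export
icc <- function(table, item, type = c("consistency", "agreement"),
                unit = c("average", "single")) {
  type <- match.arg(type); unit <- match.arg(unit)
  m <- t(ratingValues(table)[, , item, drop = TRUE]) # clips x participants
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 clips and 2 participants")
  grand <- mean(m)
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps) {
    warning("zero between-clip variance; ICC undefined for item '", item, "'")
    return(NA_real_)
  }
  if (type == "consistency") {
    if (unit == "average") (msr - mse) / msr
    else (msr - mse) / (msr + (k - 1) * mse)
  } else {
    if (unit == "average") (msr - mse) / (msr + (msc - mse) / n)
    else (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
}

#' ICC of every item
#'
#' @inheritParams icc
#' @return Named numeric vector over items.
#' @export
iccAll <- function(table, type = "consistency", unit = "average") {
  vapply(itemNames(table), function(it) icc(table, it, type, unit), 0)
}

#' Pairwise Pearson correlations between item rating profiles
#'
#' Correlates the cross-participant mean rating profiles over clips for
#' every item pair, with two-sided p-values.
#'
#' @param table a \linkS4class{RatingTable}.
#' @param clipScope optional clip ids to restrict the profiles (default all).
#' @param alpha significance level for the \code{significant} flags.
#' @return List with \code{r} (items x items, unit diagonal),
#'   \code{p} (p-values, NA on the diagonal) and \code{significant}
#'   (logical). Constant profiles give NA correlations with a warning.
#' @export
pairwiseItemCorrelations <- function(table, clipScope = NULL, alpha = 0.05) {
  mr <- meanRatings(table)
  if (!is.null(clipScope)) mr <- mr[clipScope, , drop = FALSE]
  if (nrow(mr) < 3L) stop("need at least 3 clips")
  items <- colnames(mr)
  ni <- length(items)
  r <- matrix(NA_real_, ni, ni, dimnames = list(items, items))
  p <- r
  diag(r) <- 1
  constant <- apply(mr, 2L, stats::sd) == 0
  if (any(constant))
    warning("constant rating profile(s): ",
            paste(items[constant], collapse = ", "),
            "; correlations undefined")
  for (i in seq_len(ni - 1L)) {
    for (j in (i + 1L):ni) {
      if (constant[i] || constant[j]) next
      ct <- stats::cor.test(mr[, i], mr[, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p, significant = !is.na(p) & p < alpha)
}

#' Manipulation check: do target emotions get the highest ratings?
#'
#' For each target emotion, ratings on the ten positive items are averaged
#' over that emotion's clips within participant, then compared with a
#' one-way repeated-measures ANOVA across items and post hoc paired t-tests
#' of the target item against each of the nine others. Each comparison is
#' flagged \code{"target_higher"} (target significantly higher),
#' \code{"ns"}, or \code{"reversed"} (other item significantly higher).
#'
#' @param table a \linkS4class{RatingTable}.
#' @param clips clip table (as in a \linkS4class{StudyDesign}).
#' @param alpha significance level for the post hoc flags.
#' @param correction \code{"none"} (default) or \code{"holm"} over the nine
#'   comparisons per emotion.
#' @return List per target emotion with elements \code{F}, \code{df},
#'   \code{p} (rmANOVA) and \code{posthoc} (data.frame: item, t, p, flag).
#' @export
manipulationCheck <- function(table, clips, alpha = 0.05,
                              correction = c("none", "holm")) {
  correction <- match.arg(correction)
  vals <- ratingValues(table)
  pos <- positiveItems()
  emotions <- unique(stats::na.omit(clips$target_emotion))
  out <- list()
  for (emo in emotions) {
    cid <- clips$clip_id[!is.na(clips$target_emotion) &
                           clips$target_emotion == emo]
    if (length(cid) < 1L) stop("no clips target emotion '", emo, "'")
    # participants x 10 items, averaged over the emotion's clips
    m <- apply(vals[, cid, pos, drop = FALSE], c(1L, 3L), mean)
    df <- data.frame(rating = as.vector(m),
                     participant = factor(rep(rownames(m), times = ncol(m))),
                     item = factor(rep(colnames(m), each = nrow(m))))
    fit <- stats::aov(rating ~ item + Error(participant / item), data = df)
    tab <- summary(fit)[["Error: participant:item"]][[1L]]
    Fv <- tab["item", "F value"]
    pv <- tab["item", "Pr(>F)"]
    dfs <- tab[, "Df"]
    others <- setdiff(pos, emo)
    tt <- lapply(others, function(it) {
      diffs <- m[, emo] - m[, it]
      if (stats::sd(diffs) <= 1e-10 * max(1, abs(mean(diffs)))) {
        # degenerate paired test: no variance in the differences
        if (mean(diffs) == 0) return(c(t = 0, p = 1))
        return(c(t = sign(mean(diffs)) * Inf, p = 0))
      }
      h <- stats::t.test(m[, emo], m[, it], paired = TRUE)
      c(t = unname(h$statistic), p = h$p.value)
    })
    ph <- data.frame(item = others,
                     t = vapply(tt, `[[`, 0, "t"),
                     p = vapply(tt, `[[`, 0, "p"),
                     stringsAsFactors = FALSE)
    if (correction == "holm") ph$p <- stats::p.adjust(ph$p, "holm")
    ph$flag <- ifelse(ph$p >= alpha, "ns",
                      ifelse(ph$t > 0, "target_higher", "reversed"))
    out[[emo]] <- list(F = Fv, df = unname(dfs), p = pv, posthoc = ph)
  }
  out
}

# item dissimilarities for the MDS: 1 - Pearson r between cross-participant
# mean rating profiles (or Euclidean distance between z-scored profiles)
itemDissimilarity <- function(table, items, clipScope,
                              method = c("pearson", "euclidean")) {
  method <- match.arg(method)
  mr <- meanRatings(table)[clipScope, items, drop = FALSE]
  if (method == "pearson") {
    d <- 1 - stats::cor(mr)
  } else {
    d <- as.matrix(stats::dist(t(scale(mr))))
  }
  if (anyNA(d)) stop("undefined dissimilarities (constant item profile)")
  d
}

#' Non-metric MDS embedding of the positive emotions
#'
#' Embeds the ten positive items by Kruskal's non-metric MDS on item
#' dissimilarities (1 - Pearson r between cross-participant mean rating
#' profiles over the positive clips, by default). Multiple restarts are run
#' (a classical-scaling start plus random starts under a fixed seed) and the
#' solution with the lowest Kruskal Stress-1 is kept.
#'
#' @param table a \linkS4class{RatingTable}.
#' @param items items to embed; default the ten positive emotions.
#' @param dims embedding dimensionality (>= 1).
#' @param clipScope clip ids defining the rating profiles (e.g. the 30
#'   positive clips); default all clips in the table.
#' @param dissimilarity \code{"pearson"} (1 - r) or \code{"euclidean"}.
#' @param nRestarts number of random restarts beyond the classical start.
#' @param seed integer seed making the restarts reproducible.
#' @param initial optional items x dims starting configuration added to the
#'   restart pool (used to nest solutions across dimensions).
#' @return A \linkS4class{ClusterModel} with the embedding and stress (on
#'   the [0, 1] scale); the cluster assignment is left empty.
#' @export
mdsEmbed <- function(table, items = positiveItems(), dims = 3L,
                     clipScope = NULL, dissimilarity = "pearson",
                     nRestarts = 8L, seed = 1L, initial = NULL) {
  if (dims < 1L) stop("dims must be >= 1")
  if (length(items) < dims + 1L) stop("need at least dims + 1 items")
  clipScope <- clipScope %||% clipIds(table)
  d <- itemDissimilarity(table, items, clipScope, dissimilarity)
  dOff <- d[upper.tri(d)]
  if (any(dOff <= 0)) {
    warning("non-positive dissimilarities (duplicate items?); ",
            "bumped to a small epsilon")
    eps <- 1e-6
    d[d <= 0] <- eps
    diag(d) <- 0
  }
  dd <- stats::as.dist(d)
  starts <- list(stats::cmdscale(dd, k = dims))
  if (!is.null(initial)) starts <- c(starts, list(initial))
  set.seed(deriveSeed(seed, "mds", dims))
  scaleRef <- stats::sd(as.matrix(starts[[1L]]))
  if (!is.finite(scaleRef) || scaleRef == 0) scaleRef <- mean(dOff)
  for (r in seq_len(nRestarts)) {
    starts <- c(starts, list(matrix(stats::rnorm(length(items) * dims,
                                                 0, scaleRef),
                                    length(items), dims)))
  }
  best <- NULL
  for (s in starts) {
    s <- as.matrix(s)
    if (ncol(s) < dims) s <- cbind(s, matrix(0, nrow(s), dims - ncol(s)))
    fit <- tryCatch(MASS::isoMDS(dd, y = s, k = dims, trace = FALSE,
                                 maxit = 100),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best))
    stop("non-metric MDS failed to converge from any start")
  emb <- best$points
  dimnames(emb) <- list(items, paste0("dim", seq_len(dims)))
  new("ClusterModel", embedding = emb, stress = best$stress / 100,
      assignment = character(), clusterScores = matrix(0, 0L, 0L))
}

#' Stress-by-dimension profile with nested starts
#'
#' Runs \code{\link{mdsEmbed}} for increasing dimensionality, seeding each
#' dimensionality with the previous best configuration (zero-padded), which
#' makes the reported best stress non-increasing in the embedding dimension.
#'
#' @inheritParams mdsEmbed
#' @param dimsRange integer vector of dimensionalities, e.g. \code{1:4}.
#' @return Named numeric vector of stress values.
#' @export
mdsStressProfile <- function(table, items = positiveItems(),
                             dimsRange = 1:4, clipScope = NULL,
                             dissimilarity = "pearson", nRestarts = 8L,
                             seed = 1L) {
  prev <- NULL
  out <- numeric(0)
  for (k in sort(dimsRange)) {
    fit <- mdsEmbed(table, items, k, clipScope, dissimilarity, nRestarts,
                    seed, initial = prev)
    out[as.character(k)] <- stressValue(fit)
    prev <- embeddingCoords(fit)
  }
  out
}

#' Assign embedded items to clusters
#'
#' Either k-means in the MDS space (for synthetic data with planted
#' structure) or the published manual assignment.
#'
#' @param model a \linkS4class{ClusterModel} from \code{\link{mdsEmbed}}.
#' @param method \code{"kmeans"} or \code{"manual"}.
#' @param k number of clusters for k-means.
#' @param seed seed for the k-means starts.
#' @param assignment named item -> cluster vector when \code{method =
#'   "manual"}; default the published three-cluster assignment.
#' @return The model with its \code{assignment} slot filled. k-means cluster
#'   ids are arbitrary labels \code{"C1"}... unless they match the published
#'   clusters, in which case the matching names are used.
#' @export
assignClusters <- function(model, method = c("kmeans", "manual"), k = 3L,
                           seed = 1L, assignment = defaultClusterAssignment()) {
  method <- match.arg(method)
  emb <- embeddingCoords(model)
  if (method == "manual") {
    asg <- assignment[rownames(emb)]
  } else {
    set.seed(deriveSeed(seed, "kmeans"))
    km <- stats::kmeans(emb, centers = k, nstart = 25L)
    asg <- stats::setNames(paste0("C", km$cluster), rownames(emb))
    ref <- defaultClusterAssignment()
    if (all(rownames(emb) %in% names(ref))) {
      # relabel clusters by majority overlap with the published assignment
      tab <- table(asg, ref[rownames(emb)])
      if (nrow(tab) == length(unique(ref[rownames(emb)]))) {
        mapping <- colnames(tab)[apply(tab, 1L, which.max)]
        if (!anyDuplicated(mapping))
          asg[] <- mapping[match(asg, rownames(tab))]
      }
    }
  }
  initialize(model, assignment = asg)
}

#' Per-clip cluster scores from z-transformed ratings
#'
#' Each item's ratings are z-scored across the scoped clips, then averaged
#' over the items of each cluster, giving one score per cluster per clip.
#' At the \code{"per_participant"} level the z-transform is applied within
#' each participant's ratings; at the \code{"cross_participant"} level it is
#' applied to the cross-participant mean ratings.
#'
#' @param table a \linkS4class{RatingTable}.
#' @param assignment named item -> cluster vector.
#' @param clipScope clip ids over which to z-score (default all clips).
#' @param level \code{"cross_participant"} or \code{"per_participant"}.
#' @return clips x clusters matrix, or (per participant) a participants x
#'   clips x clusters array. Zero-variance items are excluded with a
#'   warning; scores average the remaining items.
#' @export
clusterScores <- function(table, assignment = defaultClusterAssignment(),
                          clipScope = NULL,
                          level = c("cross_participant", "per_participant")) {
  level <- match.arg(level)
  clipScope <- clipScope %||% clipIds(table)
  clusters <- unique(assignment)
  scoreOne <- function(m) { # clips x items matrix of (mean) ratings
    m <- m[clipScope, names(assignment), drop = FALSE]
    sds <- apply(m, 2L, stats::sd)
    if (any(sds == 0)) {
      warning("zero-variance item(s) excluded from cluster scores: ",
              paste(colnames(m)[sds == 0], collapse = ", "))
    }
    z <- apply(m, 2L, zScore)
    z[, sds == 0] <- NA_real_
    out <- sapply(clusters, function(cl) {
      cols <- names(assignment)[assignment == cl]
      rowMeans(z[, cols, drop = FALSE], na.rm = TRUE)
    })
    rownames(out) <- clipScope
    out
  }
  if (level == "cross_participant") return(scoreOne(meanRatings(table)))
  vals <- ratingValues(table)
  pids <- participantIds(table)
  res <- array(NA_real_, dim = c(length(pids), length(clipScope),
                                 length(clusters)),
               dimnames = list(pids, clipScope, clusters))
  for (p in pids) res[p, , ] <- scoreOne(vals[p, , ])
  res
}
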