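# Labeling protocols and cross-validated classification.

epochGrid <- function(clipIds, epochsPerClip = 30L) {
  data.frame(clip_id = rep(clipIds, each = epochsPerClip),
             epoch = rep(seq_len(epochsPerClip), times = length(clipIds)),
             stringsAsFactors = FALSE)
}

test_that("median split is exactly balanced and rank-correct", {
  cid <- sprintf("c%02d", 1:30)
  info <- epochGrid(cid)
  vals <- stats::setNames(sample(30), cid) # distinct ratings
  lab <- medianSplitLabels(info, vals)
  expect_equal(as.vector(table(lab)), c(450L, 450L))
  # clips ranked 16..30 are high
  highClips <- names(sort(vals))[16:30]
  expect_true(all(lab[info$clip_id %in% highClips] == "high"))
  expect_true(all(lab[!info$clip_id %in% highClips] == "low"))
  # epochs of one clip share a label when ratings are distinct
  for (cc in cid)
    expect_equal(length(unique(lab[info$clip_id == cc])), 1L)
})

test_that("median split stays 450/450 under heavy ties, deterministically", {
  cid <- sprintf("c%02d", 1:30)
  info <- epochGrid(cid)
  vals <- stats::setNames(c(rep(3, 20), rep(5, 10)), cid) # ties at the median
  lab1 <- medianSplitLabels(info, vals)
  lab2 <- medianSplitLabels(info, vals)
  expect_equal(as.vector(table(lab1)), c(450L, 450L))
  expect_identical(lab1, lab2)
  # a tie-straddling clip is the only one with mixed labels
  mixed <- vapply(cid, function(cc)
    length(unique(lab1[info$clip_id == cc])) > 1L, TRUE)
  expect_lte(sum(mixed), 1L)
  expect_error(medianSplitLabels(info, stats::setNames(rep(1, 30), cid)),
               "identical")
})

test_that("cluster split equals the item split for a single-item cluster", {
  cid <- sprintf("c%02d", 1:30)
  info <- epochGrid(cid)
  set.seed(13)
  joy <- stats::setNames(sample(1:7, 30, replace = TRUE), cid)
  # a single-item cluster's score is the item's z-scores: same ordering
  sc <- matrix(as.vector(scale(joy)), 30, 1,
               dimnames = list(cid, "playfulness"))
  expect_identical(clusterSplitLabels(info, sc, "playfulness"),
                   medianSplitLabels(info, joy))
})

test_that("anti-correlated cluster scores give complementary labels", {
  cid <- sprintf("c%02d", 1:30)
  info <- epochGrid(cid)
  set.seed(17)
  s <- rnorm(30)
  sc <- cbind(playfulness = s, harmony = -s)
  rownames(sc) <- cid
  a <- clusterSplitLabels(info, sc, "playfulness")
  b <- clusterSplitLabels(info, sc, "harmony")
  expect_true(mean((a == "high") != (b == "high")) > 0.95)
})

test_that("pairwise cluster labels follow score differences and drop ties", {
  cid <- c("a", "b", "c")
  sc <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0.5, 0.5, 0))
  colnames(sc) <- clusterNames()
  info <- epochGrid(cid, 2L)
  expect_warning(pw <- pairwiseClusterLabels(info, sc, "encouragement",
                                             "playfulness"), "tied")
  expect_equal(as.vector(pw$classSizes), c(1L, 1L))
  expect_equal(sum(pw$keep), 4L)
  expect_equal(as.character(pw$clipLabels[c("a", "b")]),
               c("encouragement", "playfulness"))
  sc0 <- sc; sc0[, 1:2] <- 0
  expect_error(pairwiseClusterLabels(info, sc0, "encouragement",
                                     "playfulness"), "tied")
})

test_that("planted synthetic preset labels playfulness-dominant clips correctly", {
  st <- smallStudy()
  d <- st$design
  pos <- d@clips[d@clips$category == "positive", ]
  sc <- clusterScores(st$ratings, clipScope = pos$clip_id)
  info <- epochGrid(pos$clip_id, 1L)
  pw <- pairwiseClusterLabels(info, sc, "playfulness", "encouragement")
  planted <- defaultClusterAssignment()[pos$target_emotion]
  # clips targeting playfulness emotions are built to score highest there
  playClips <- pos$clip_id[planted == "playfulness"]
  expect_true(all(pw$clipLabels[playClips] == "playfulness"))
  encClips <- pos$clip_id[planted == "encouragement"]
  expect_true(all(pw$clipLabels[encClips] == "encouragement"))
})

test_that("perfectly separable features classify at >= 99%", {
  set.seed(19)
  n <- 400L
  x <- matrix(rnorm(n * 20), n)
  y <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  x[y == "high", 1:5] <- x[y == "high", 1:5] + 10
  res <- crossvalClassify(x, y, folds = 10L, seed = 1L)
  expect_gte(accuracy(res), 99)
  expect_length(foldAccuracies(res), 10L)
  expect_equal(accuracy(res), mean(foldAccuracies(res)))
})

test_that("uninformative features stay near chance and shuffles destroy signal", {
  set.seed(23)
  n <- 300L
  x <- matrix(rnorm(n * 40), n)
  y <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  res <- crossvalClassify(x, y, folds = 10L, seed = 2L)
  expect_gt(accuracy(res), 40)
  expect_lt(accuracy(res), 60)
  # informative features, then label shuffling wipes the signal
  x2 <- x; x2[y == "high", 1:10] <- x2[y == "high", 1:10] + 1.5
  expect_gt(accuracy(crossvalClassify(x2, y, folds = 10L, seed = 2L)), 90)
})

test_that("shuffling epoch labels destroys above-chance accuracy at n = 900", {
  ep <- smallEpochTensor()
  st <- smallStudy()
  pos <- st$design@clips$clip_id[st$design@clips$category == "positive"]
  rmat <- ratingValues(st$ratings)["P01", pos, , drop = TRUE]
  lab <- medianSplitLabels(rowInfo(ep),
                           stats::setNames(rmat[, "joy"], rownames(rmat)))
  fm <- featureMatrix(ep)
  accs <- vapply(1:5, function(i) {
    set.seed(200 + i)
    accuracy(crossvalClassify(fm, sample(lab), folds = 10L, seed = i))
  }, 0)
  expect_lt(abs(mean(accs) - 50), 3)
})

test_that("accuracy is invariant under global affine feature transforms", {
  set.seed(29)
  n <- 200L
  x <- matrix(rnorm(n * 15), n)
  y <- factor(rep(c("low", "high"), each = n / 2))
  x[y == "high", 1:4] <- x[y == "high", 1:4] + 1
  a1 <- accuracy(crossvalClassify(x, y, folds = 5L, seed = 7L))
  a2 <- accuracy(crossvalClassify(x * 250 - 17, y, folds = 5L, seed = 7L))
  expect_equal(a1, a2)
})

test_that("fold assignment and accuracies reproduce under a fixed seed", {
  set.seed(31)
  x <- matrix(rnorm(240 * 10), 240)
  y <- factor(rep(c("low", "high"), 120))
  r1 <- crossvalClassify(x, y, folds = 6L, seed = 11L)
  r2 <- crossvalClassify(x, y, folds = 6L, seed = 11L)
  expect_identical(foldAccuracies(r1), foldAccuracies(r2))
  r3 <- crossvalClassify(x, y, folds = 6L, seed = 12L)
  expect_false(identical(foldAccuracies(r1), foldAccuracies(r3)))
})

test_that("degenerate label sets are rejected", {
  x <- matrix(rnorm(60 * 4), 60)
  expect_error(crossvalClassify(x, factor(rep("a", 60)), folds = 10L), "binary")
  y <- factor(c(rep("a", 55), rep("b", 5)))
  expect_error(crossvalClassify(x, y, folds = 10L), "per class")
})

test_that("grand average over copies of one participant equals the individual run", {
  ep <- smallEpochTensor()
  st <- smallStudy()
  pos <- st$design@clips$clip_id[st$design@clips$category == "positive"]
  rmat <- ratingValues(st$ratings)["P01", pos, , drop = TRUE]
  lab <- medianSplitLabels(rowInfo(ep),
                           stats::setNames(rmat[, "joy"], rownames(rmat)))
  single <- crossvalClassify(ep, lab, seed = 3L)
  ga <- grandAverageClassify(list(ep, ep, ep), lab, seed = 3L)
  expect_equal(accuracy(ga), accuracy(single))
  expect_equal(ga@participant, "grand_average")
  # misaligned grids are rejected
  ep2 <- ep
  ep2@rowData$epoch <- rev(ep2@rowData$epoch)
  expect_error(grandAverageFeatures(list(ep, ep2)), "misaligned")
})
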