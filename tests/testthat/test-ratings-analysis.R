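# Reliability, similarity, manipulation check, MDS and cluster scores.

test_that("ICC matches the variance-components closed form on a toy matrix", {
  # 3 clips x 3 raters, worked out by hand: MSR = 76/9, MSE = 4/9,
  # consistency/average ICC = 18/19
  m <- rbind(c(2, 4, 3), c(4, 5, 6), c(6, 7, 6)) # clips x raters
  rt <- ratingTableFromMatrix(m)
  expect_equal(icc(rt, "joy"), 18 / 19, tolerance = 1e-12)
  # independent route: two-way ANOVA mean squares via aov
  df <- data.frame(rating = as.vector(m),
                   clip = factor(rep(1:3, times = 3)),
                   rater = factor(rep(1:3, each = 3)))
  tab <- anova(stats::lm(rating ~ clip + rater, data = df))
  msr <- tab["clip", "Mean Sq"]; mse <- tab["Residuals", "Mean Sq"]
  expect_equal(icc(rt, "joy"), (msr - mse) / msr, tolerance = 1e-12)
  # single-measure and agreement variants stay below the average form
  expect_lt(icc(rt, "joy", unit = "single"), icc(rt, "joy"))
  expect_lte(icc(rt, "joy", type = "agreement"), icc(rt, "joy"))
})

test_that("consistency ICC is invariant to shifting and scaling raters", {
  m <- rbind(c(1, 2, 2), c(3, 3, 4), c(5, 6, 5), c(2, 3, 2))
  base <- icc(ratingTableFromMatrix(m), "joy")
  expect_equal(icc(ratingTableFromMatrix(m + 1), "joy"), base)
  # rescaling all ratings by a common factor
  expect_equal(icc(ratingTableFromMatrix(m * 1L), "joy"), base)
  m2 <- m; m2[] <- as.integer(round(m * 1.0)) # identity rescale stays exact
  expect_equal(icc(ratingTableFromMatrix(m2), "joy"), base)
})

test_that("independent noise ratings give near-zero ICC at many clips", {
  set.seed(31)
  vals <- vapply(1:6, function(s) {
    m <- matrix(sample(1:7, 50 * 4, replace = TRUE), 50, 4)
    icc(ratingTableFromMatrix(m), "joy")
  }, 0)
  expect_true(all(abs(vals) < 0.35))
  expect_lt(abs(mean(vals)), 0.15)
})

test_that("zero between-clip variance makes the ICC undefined", {
  m <- matrix(4L, 5, 3)
  expect_warning(v <- icc(ratingTableFromMatrix(m), "joy"), "undefined")
  expect_true(is.na(v))
})

test_that("pairwise item correlations handle duplicates, negations, and constants", {
  clips <- 12L
  set.seed(33)
  a <- sample(1:7, clips, replace = TRUE)
  im <- cbind(a = a, dup = a, neg = 8L - a, const = rep(4L, clips))
  expect_warning(pc <- pairwiseItemCorrelations(ratingTableFromItems(im)),
                 "constant")
  expect_equal(pc$r["a", "dup"], 1)
  expect_equal(pc$r["a", "neg"], -1)
  expect_true(is.na(pc$r["a", "const"]))
  expect_true(all(diag(pc$r) == 1))
  expect_equal(pc$r, t(pc$r))
  expect_true(pc$significant["a", "dup"])
})

test_that("the correlation matrix of complete profiles is positive semidefinite", {
  rt <- smallStudy()$ratings
  r <- pairwiseItemCorrelations(rt)$r
  expect_equal(r, t(r))
  expect_gt(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("manipulation check flags strong targets and ties correctly", {
  d <- shortClipDesign(nParticipants = 6L, seed = 41L)
  rt <- generateRatings(d, latentEmotionModel(targetBoost = 3,
                                              participantNoiseSd = 0.3,
                                              itemNoiseSd = 0.1))
  mc <- manipulationCheck(rt, d@clips)
  expect_setequal(names(mc), positiveItems())
  for (emo in c("joy", "awe", "serenity")) {
    expect_lt(mc[[emo]]$p, 0.001)
    expect_true(all(mc[[emo]]$posthoc$flag == "target_higher"))
    expect_equal(nrow(mc[[emo]]$posthoc), 9L)
  }
  # identical columns give t = 0, p = 1, flagged ns
  v <- ratingValues(rt)
  v[, , "gratitude"] <- v[, , "hope"]
  rt2 <- new("RatingTable", values = v)
  mc2 <- manipulationCheck(rt2, d@clips)
  row <- mc2$hope$posthoc[mc2$hope$posthoc$item == "gratitude", ]
  expect_equal(row$t, 0)
  expect_equal(row$p, 1)
  expect_equal(row$flag, "ns")
})

test_that("MDS embeds the planted blocks at low stress and k-means recovers them", {
  d <- shortClipDesign(nParticipants = 6L, seed = 43L)
  rt <- generateRatings(d)
  pos <- d@clips$clip_id[d@clips$category == "positive"]
  fit <- mdsEmbed(rt, dims = 3L, clipScope = pos, seed = 2L)
  expect_lt(stressValue(fit), 0.01) # near-perfectly 3-embeddable blocks
  expect_equal(dim(embeddingCoords(fit)), c(10L, 3L))
  fit <- assignClusters(fit, "kmeans", seed = 2L)
  asg <- clusterAssignment(fit)
  truth <- defaultClusterAssignment()[names(asg)]
  ari <- e1071::classAgreement(table(asg, truth))$crand
  expect_equal(ari, 1)
  # manual assignment passthrough
  man <- assignClusters(fit, "manual")
  expect_identical(clusterAssignment(man), truth)
})

test_that("MDS stress is non-increasing in the embedding dimension", {
  for (seed in c(47L, 53L)) {
    d <- shortClipDesign(nParticipants = 4L, seed = seed)
    rt <- generateRatings(d, latentEmotionModel(participantNoiseSd = 1.5,
                                                itemNoiseSd = 0.6))
    pos <- d@clips$clip_id[d@clips$category == "positive"]
    prof <- mdsStressProfile(rt, dimsRange = 1:4, clipScope = pos,
                             seed = seed)
    expect_true(all(diff(prof) <= 1e-8))
  }
})

test_that("MDS restarts are deterministic under a fixed seed", {
  rt <- smallStudy()$ratings
  f1 <- mdsEmbed(rt, dims = 2L, seed = 9L)
  f2 <- mdsEmbed(rt, dims = 2L, seed = 9L)
  expect_identical(embeddingCoords(f1), embeddingCoords(f2))
  expect_identical(stressValue(f1), stressValue(f2))
})

test_that("cluster scores match hand arithmetic and are centered", {
  # written-out 3-clip toy table, one 2-item and one 1-item cluster
  im <- cbind(love = c(2L, 4L, 6L), serenity = c(1L, 5L, 6L),
              joy = c(3L, 3L, 6L))
  rt <- ratingTableFromItems(im, nParticipants = 2L)
  asg <- c(love = "harmony", serenity = "harmony", joy = "playfulness")
  sc <- clusterScores(rt, asg)
  zh <- (cbind(scale(im[, "love"]), scale(im[, "serenity"])))
  expect_equal(sc[, "harmony"], rowMeans(zh), ignore_attr = TRUE)
  # single-item cluster equals that item's z-scores
  expect_equal(sc[, "playfulness"], as.vector(scale(im[, "joy"])),
               ignore_attr = TRUE)
  expect_equal(colMeans(sc), c(harmony = 0, playfulness = 0),
               tolerance = 1e-10)
})

test_that("cluster score column means vanish on the scoped clips", {
  st <- smallStudy()
  pos <- st$design@clips$clip_id[st$design@clips$category == "positive"]
  sc <- clusterScores(st$ratings, clipScope = pos)
  expect_true(all(abs(colMeans(sc)) < 1e-10))
  scp <- clusterScores(st$ratings, clipScope = pos,
                       level = "per_participant")
  expect_equal(dim(scp), c(2L, 30L, 3L))
  for (p in 1:2) expect_true(all(abs(colMeans(scp[p, , ])) < 1e-10))
})

test_that("zero-variance items are excluded from cluster scores with a warning", {
  im <- cbind(love = rep(4L, 4), serenity = c(1L, 3L, 5L, 7L))
  rt <- ratingTableFromItems(im)
  asg <- c(love = "harmony", serenity = "harmony")
  expect_warning(sc <- clusterScores(rt, asg), "zero-variance")
  # score falls back to the remaining item
  expect_equal(sc[, "harmony"], as.vector(scale(im[, "serenity"])),
               ignore_attr = TRUE)
})
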