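# Ranking metrics and cross-validation protocols.

test_that("AUC matches hand-computed and brute-force values", {
  expect_identical(aucScore(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_identical(aucScore(c(1, 2, 3), c(1, 0, 0)), 0)
  expect_equal(aucScore(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(aucScore(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)  # all tied
  set.seed(10)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    s <- sample(round(runif(n), 2))  # duplicates force tie handling
    l <- rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) next
    expect_equal(aucScore(s, l), bruteForceAuc(s, l), tolerance = 1e-12)
  }
  expect_error(aucScore(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  s <- runif(200); l <- rbinom(200, 1, 0.3)
  expect_equal(aucScore(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))),
               tolerance = 1e-12)
})

test_that("topN counts actives with truncation and deterministic ties", {
  r <- topN(scores = 20:1, labels = c(1, 0, 1, rep(0, 17)), N = 10)
  expect_identical(r, list(topN = 2L, hitN = 1L))
  expect_identical(topN(1:5, rep(0, 5), N = 3), list(topN = 0L, hitN = 0L))
  # fewer candidates than N: all are used
  expect_identical(topN(c(1, 2), c(1, 1), N = 10), list(topN = 2L, hitN = 1L))
  # ties broken by id, ascending
  expect_identical(topN(c(1, 1, 1), c(0, 1, 0), N = 1,
                        ids = c("a", "b", "c"))$topN, 0L)
  expect_identical(topN(c(1, 1, 1), c(0, 1, 0), N = 1,
                        ids = c("b", "a", "c"))$topN, 1L)
  expect_error(topN(1:3, c(1, 0, 0), N = 0), "N must be")
})

test_that("random-ranking hit rate has the hypergeometric closed form", {
  expect_equal(randomHitRate(100, 0, 10), 0)
  expect_identical(randomHitRate(8, 2, 10), 1)  # K - m < N
  # Monte-Carlo agreement on one fixture pool
  rec <- fixRecords()
  pool <- rec[rec$target == screeningTargets(fixDataset())[1], ]
  K <- nrow(pool); m <- sum(pool$label)
  set.seed(12)
  hits <- vapply(1:400, function(i)
    topN(runif(K), pool$label, N = 10)$hitN, 0L)
  expect_equal(mean(hits), randomHitRate(K, m, 10), tolerance = 0.08)
})

test_that("outer CV splits at the target level with derived seeds", {
  ds <- fixDataset()
  cv <- outerCv(ds, testFraction = 0.1, replicates = 4, learner = "random",
                seed = 42)
  pt <- cvPerTarget(cv)
  # 8 targets at fraction 0.1 -> exactly 1 test target per replicate
  expect_identical(cv@settings$n_test, 1L)
  expect_identical(nrow(pt), 4L)
  expect_true(all(pt$hitN == (pt$topN >= 1L)))
  # rerun reproduces the same splits and metrics
  cv2 <- outerCv(ds, testFraction = 0.1, replicates = 4, learner = "random",
                 seed = 42)
  expect_identical(cvPerTarget(cv2), pt)
  # aggregates are recomputable from the per-target table
  agg <- cvAggregates(cv)
  expect_equal(agg$pct_topN,
               mean(tapply(pt$hitN, pt$replicate, mean)))
  expect_error(outerCv(ds, testFraction = 0.99, replicates = 1), "training")
})

test_that("a fitted scorer beats the random baseline on held-out pools", {
  ds <- fixDataset()
  cvL <- outerCv(ds, replicates = 4, featureGroup = "SM-5_11",
                 learner = "lasso", seed = 5)
  cvR <- outerCv(ds, replicates = 4, learner = "random", seed = 5)
  expect_gt(cvAggregates(cvL)$mean_auc, cvAggregates(cvR)$mean_auc + 0.15)
})

test_that("learning curve at full size reproduces the outer-CV protocol", {
  ds <- fixDataset()
  cv <- outerCv(ds, replicates = 3, featureGroup = "Mact", learner = "lasso",
                seed = 7)
  lc <- learningCurve(ds, trainSizes = c(3, 7), replicates = 3,
                      featureGroup = "Mact", learner = "lasso", seed = 7)
  expect_identical(nrow(lc), 2L)
  # 8 targets, 1 held out: size 7 is the full training split
  expect_equal(lc$mean_auc[2], cvAggregates(cv)$mean_auc)
  expect_error(learningCurve(ds, trainSizes = 0), "sizes")
  expect_error(learningCurve(ds, trainSizes = 100), "exceeds")
})

test_that("distance subsampling removes near-test targets only", {
  targets <- screeningTargets(fixDataset())
  train <- targets[1:6]; test <- targets[7:8]
  kept <- distanceSubsample(train, test, minDist = 1)
  expect_setequal(kept, train)  # all-distinct targets: full set retained
  expect_equal(attr(kept, "retained_fraction"), 1)
  # a training target identical to a test target is removed at minDist 1
  kept2 <- distanceSubsample(c(train, test[1]), test, minDist = 1)
  expect_setequal(kept2, train)
  # uniform mode matches the distance-mode count
  kept3 <- distanceSubsample(train, test, minDist = 3, mode = "distance")
  kept4 <- distanceSubsample(train, test, minDist = 3, mode = "uniform",
                             seed = 2)
  expect_identical(length(kept4), length(kept3))
  expect_true(all(vapply(kept3, function(tr)
    min(targetDistance(rep(tr, 2), test)), 0L) >= 3L))
  expect_error(distanceSubsample(train, train, minDist = 1), "minDist|distance")
  expect_error(distanceSubsample(train, test, minDist = 0), "minDist")
})
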