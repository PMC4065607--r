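# Learners, ensemble combination and prediction contracts.

test_that("lasso recovers a planted main effect and ignores noise columns", {
  set.seed(5)
  n <- 2000
  p44 <- sample(c("A", "B"), n, replace = TRUE)
  lab <- as.integer(runif(n) < ifelse(p44 == "A", 0.6, 0.1))
  rec <- makeRecords(p44 = p44,
                     p77 = sample(c("V", "K", "T"), n, replace = TRUE),
                     p30 = sample(c("N", "K", "R"), n, replace = TRUE),
                     label = lab)
  fm <- encodeBin1(rec)
  sc <- fitLasso(fm, lab, innerFolds = 3, seed = 1, group = "SM-5_11")
  ct <- coefTable(sc)
  expect_gt(ct$coef[ct$feature == "P44=A"] - ct$coef[ct$feature == "P44=B"], 0.5)
  noise <- ct$coef[grepl("^P(30|77)=", ct$feature)]
  expect_true(all(abs(noise) < 0.3))
  expect_error(fitLasso(fm, rep(1L, n)), "degenerate")
})

test_that("permuted labels score at chance level in inner CV", {
  set.seed(6)
  rec <- fixRecords()
  perm <- sample(rec$label)
  fm <- selectGroup(fixBin2(), "SeqMact")
  sc <- fitLasso(fm, perm, innerFolds = 3, seed = 2)
  icv <- innerCVRecord(sc)
  expect_identical(icv$measure, "auc")
  # max over the path is selection-biased upward; still near chance
  expect_lt(max(icv$cvm), 0.6)
})

test_that("row duplication leaves the selected ranking unchanged", {
  rec <- fixRecords()
  pool <- rec[rec$target == screeningTargets(fixDataset())[1], ]
  fm <- selectGroup(fixBin2(), "SM-5_11")
  grid <- exp(seq(log(5e-2), log(5e-4), length.out = 10))
  sc1 <- fitLasso(fm, rec$label, lambdaGrid = grid, innerFolds = 3, seed = 1)
  rec2 <- rbind(rec, rec)
  b2 <- addInteractions(encodeBin1(rec2), minSupport = 200)
  sc2 <- fitLasso(selectGroup(b2, "SM-5_11"), rec2$label, lambdaGrid = grid,
                  innerFolds = 3, seed = 1)
  r1 <- rankCandidates(sc1, pool)
  r2 <- rankCandidates(sc2, pool)
  expect_identical(r1$variant_id, r2$variant_id)
})

test_that("boosted trees learn a planted XOR that main effects cannot", {
  set.seed(7)
  n <- 3000
  p44 <- sample(c("A", "B"), n, replace = TRUE)
  p77 <- sample(c("V", "K"), n, replace = TRUE)
  lab <- as.integer(xor(p44 == "A", p77 == "V"))
  lab <- ifelse(runif(n) < 0.05, 1L - lab, lab)  # 5% label noise
  rec <- makeRecords(p44 = p44, p77 = p77, label = lab)
  fm <- encodeBin1(rec)
  gbm <- fitGbm(fm, lab, innerFolds = 3, seed = 1)
  lin <- fitLasso(fm, lab, innerFolds = 3, seed = 1)
  aucG <- aucScore(predictActivity(gbm, rec), lab)
  aucL <- aucScore(predictActivity(lin, rec), lab)
  expect_gt(aucG, 0.85)
  expect_lt(abs(aucL - 0.5), 0.12)
  expect_gt(innerCVRecord(gbm)$chosen$cv_auc, 0.8)
})

test_that("inner-CV AUC degrades monotonically with label noise", {
  set.seed(8)
  n <- 2500
  p44 <- sample(c("A", "B"), n, replace = TRUE)
  base <- as.integer(p44 == "A")
  aucs <- vapply(c(0.05, 0.2, 0.45), function(eps) {
    lab <- ifelse(runif(n) < eps, 1L - base, base)
    rec <- makeRecords(p44 = p44, label = lab)
    sc <- fitGbm(encodeBin1(rec), lab, innerFolds = 3, seed = 1)
    innerCVRecord(sc)$chosen$cv_auc
  }, 0)
  expect_true(all(diff(aucs) < 0))
})

test_that("fixed seeds give bit-identical boosted-tree predictions", {
  rec <- fixRecords()[1:2000, ]
  fm <- encodeBin1(rec)
  s1 <- fitGbm(fm, rec$label[1:2000], innerFolds = 3, seed = 11)
  s2 <- fitGbm(fm, rec$label[1:2000], innerFolds = 3, seed = 11)
  expect_identical(predictActivity(s1, rec), predictActivity(s2, rec))
})

test_that("the ensemble is a per-pool fractional-rank mean", {
  rec <- fixRecords()
  fm <- selectGroup(fixBin2(), "SM-5_11")
  fp <- mndesign:::fingerprintRecords(rec)
  la <- fitLasso(fm, rec$label, innerFolds = 3, seed = 1, fingerprint = fp)
  gb <- fitGbm(fm, rec$label, innerFolds = 3, seed = 1, fingerprint = fp)
  ens <- fitEnsemble(list(la, gb))
  pool <- rec[rec$target == screeningTargets(fixDataset())[2], ]
  got <- predictActivity(ens, pool)
  r <- function(x) rank(x, ties.method = "average") / length(x)
  want <- (r(predictActivity(la, pool)) + r(predictActivity(gb, pool))) / 2
  expect_equal(got, want)
  # single member: ordering identical to the member's
  one <- fitEnsemble(list(la))
  expect_identical(order(-predictActivity(one, pool)),
                   order(-predictActivity(la, pool)))
  # mismatched training data is refused
  laOther <- fitLasso(fm, rec$label, innerFolds = 3, seed = 1,
                      fingerprint = "other")
  expect_error(fitEnsemble(list(la, laOther)), "fingerprint")
})

test_that("ranking conserves candidates, ignores input order, tops the max", {
  rec <- fixRecords()
  pool <- rec[rec$target == screeningTargets(fixDataset())[3], ]
  sc <- fitLasso(selectGroup(fixBin2(), "SM-5_11"), rec$label,
                 innerFolds = 3, seed = 1)
  rk <- rankCandidates(sc, pool)
  expect_identical(nrow(rk), nrow(pool))
  expect_setequal(rk$variant_id, pool$variant_id)
  expect_identical(rk$score[1], max(rk$score))
  set.seed(9)
  shuf <- pool[sample(nrow(pool)), ]
  expect_identical(rankCandidates(sc, shuf)$variant_id, rk$variant_id)
  # scores are independent of candidate input order
  expect_equal(predictActivity(sc, shuf),
               predictActivity(sc, pool)[match(shuf$variant_id,
                                               pool$variant_id)])
})

test_that("trainScorer wires encodings, groups and members together", {
  ds <- fixDataset()
  sc <- trainScorer(ds, group = "Mact", learner = "lasso", seed = 1)
  expect_identical(scorerKind(sc), "lasso")
  expect_identical(scorerGroup(sc), "Mact")
  expect_identical(nrow(sc@encoder$columnData), 2L)
  ens <- trainScorer(ds, group = "SM-5_11", learner = "ensemble", seed = 1)
  expect_identical(scorerKind(ens), "ensemble")
  expect_length(ens@fit, 2L)
  rec <- screeningRecords(ds)
  expect_length(predictActivity(ens, rec[1:30, ]), 30L)
})
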