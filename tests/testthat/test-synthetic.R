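# Generative simulator: libraries, ground truth, datasets.

test_that("module libraries cover their region spaces with active modules", {
  libs <- simulateModuleLibraries(seed = 3,
                                  sizes = c(p5N3 = 96L, p11N4 = 256L))
  for (lib in libs) {
    act <- moduleActivities(lib)
    expect_true(all(act >= 0 & act <= 1))
    expect_true(all(apply(act, 2, max) >= 0.25))
    lat <- moduleActivities(lib, latent = TRUE)
    expect_identical(dim(lat), dim(act))
  }
  expect_identical(ncol(moduleActivities(libs$p5)), 64L)
  expect_identical(ncol(moduleActivities(libs$p11)), 256L)
  libs2 <- simulateModuleLibraries(seed = 3,
                                   sizes = c(p5N3 = 96L, p11N4 = 256L))
  expect_identical(moduleActivities(libs2$p5), moduleActivities(libs$p5))
  expect_identical(moduleResidues(libs2$p11), moduleResidues(libs$p11))
})

test_that("ground-truth activity is additive, clipped and seed-stable", {
  m0 <- groundTruthModel(seed = 101, params = list(sigma = 0))
  ds <- fixDataset()
  rec <- screeningRecords(ds)
  cand <- rec[1:200, c("variant_id", "p5_module", "p11_module",
                       paste0("p", c(30, 32, 33, 38, 40, 44, 68, 70, 75, 77)))]
  target <- rec$target[1]
  gt1 <- groundTruthActivity(fixModel(), cand, target, noiseSeed = 9)
  gt2 <- groundTruthActivity(fixModel(), cand, target, noiseSeed = 9)
  expect_identical(gt1, gt2)
  expect_true(all(gt1$score >= 0 & gt1$score <= 1))
  expect_identical(gt1$label, as.integer(gt1$score >= 0.25))
  expect_true(all(gt1$label[gt1$strong] == 1L))  # strong implies active
  # sigma = 0: repeated calls identical regardless of noise seed
  z1 <- groundTruthActivity(m0, cand, target, noiseSeed = 1)
  z2 <- groundTruthActivity(m0, cand, target, noiseSeed = 2)
  expect_identical(z1$score, z2$score)
})

test_that("the planted 44R+77R pair is deleterious in every context", {
  # same seed as the fixture model so the candidates' modules are the ones
  # the pools were assembled from; neutral baseline keeps latent scores away
  # from the [0,1] clip so the pair contrast is visible
  m0 <- groundTruthModel(seed = 101, params = list(sigma = 0, b0 = 0))
  ds <- fixDataset(); rec <- screeningRecords(ds)
  cand <- unique(rec[c("variant_id", "p5_module", "p11_module",
                       paste0("p", c(30, 32, 33, 38, 40, 44, 68, 70, 75,
                                     77)))])[1:300, ]
  cand$p44 <- "R"; cand$p77 <- "R"
  counter <- cand; counter$p77 <- "I"
  t <- rec$target[1]
  withPair <- groundTruthActivity(m0, cand, t)$score
  without <- groundTruthActivity(m0, counter, t)$score
  # the [0,1] squash censors variants whose latent score is far below zero
  # in both arms; wherever the counterfactual is not censored, the pair
  # carrier scores strictly below it
  free <- without > 0 & without < 1
  expect_gt(sum(free), 100)
  expect_true(all(withPair[free] < without[free]))
  expect_gt(mean(without[free] - withPair[free]), 0.2)
})

test_that("a zeroed-effects world depends on modules only", {
  mz <- groundTruthModel(seed = 101, params = list(sigma = 0),
                         zeroSequenceEffects = TRUE)
  expect_identical(nrow(mz@nonspecific), 0L)
  expect_identical(nrow(mz@m2m), 0L)
  ds <- fixDataset(); rec <- screeningRecords(ds)
  cand <- rec[1:50, c("variant_id", "p5_module", "p11_module",
                      paste0("p", c(30, 32, 33, 38, 40, 44, 68, 70, 75, 77)))]
  mutated <- cand
  mutated$p44 <- "F"; mutated$p32 <- "K"  # worst planted mutations
  t <- rec$target[1]
  expect_identical(groundTruthActivity(mz, cand, t)$score,
                   groundTruthActivity(mz, mutated, t)$score)
})

test_that("screening datasets meet the campaign's descriptive statistics", {
  ds <- fixDataset()
  rec <- screeningRecords(ds)
  pos <- tapply(rec$label, rec$target, sum)
  size <- tapply(rec$label, rec$target, length)
  expect_true(all(pos >= 1))  # every target has at least one positive
  expect_lt(abs(mean(size) - 1160) / 1160, 0.1)
  expect_true(all(rec$measured == (rec$label == 1L)))
  expect_true(all(rec$activity[rec$label == 1L] >= 0.25))
  # byte-identical regeneration and TSV export under a fixed seed
  ds2 <- generateScreeningDataset(fixModel(), nTargets = 8, seed = 101)
  expect_identical(screeningRecords(ds2), rec)
  f1 <- tempfile(); f2 <- tempfile()
  writeScreeningTSV(ds, f1); writeScreeningTSV(ds2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("specificity datasets have the stated shape and invariants", {
  sp <- generateSpecificityDataset(nMutants = 400, seed = 5)
  expect_identical(dim(sp$activities), c(401L, 64L))  # + wild-type row
  expect_identical(rownames(sp$activities)[1], "WT")
  expect_true(all(rowSums(sp$activities >= sp$tau) >= 1))
  expect_true(all(sp$activities >= 0 & sp$activities <= 1))
  sp2 <- generateSpecificityDataset(nMutants = 400, seed = 5)
  expect_identical(sp2$activities, sp$activities)
  # candidate-space mode admits mutants with no active target
  spc <- generateSpecificityDataset(nMutants = 2000, seed = 5,
                                    ensureActive = FALSE)
  expect_gt(sum(rowSums(spc$activities >= spc$tau) == 0), 0)
  pred <- simulatePredictedActivities(spc, seed = 5)
  expect_identical(dim(pred), dim(spc$activities))
  expect_identical(pred, simulatePredictedActivities(spc, seed = 5))
})

test_that("ground truth dumps to JSON for counterfactual oracles", {
  f <- tempfile(fileext = ".json")
  writeGroundTruth(fixModel(), f)
  gt <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(gt$params$tau_active, 0.25)
  expect_true(all(c("nonspecific", "m2m", "m2t", "p5_modules") %in% names(gt)))
  m2m <- as.data.frame(gt$m2m)
  expect_true(any(m2m$pos1 == 44 & m2m$res1 == "R" &
                    m2m$pos2 == 77 & m2m$res2 == "R" & m2m$effect < 0))
})
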