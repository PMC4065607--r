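## Per-target ranking metrics and cross-validation protocols.
##
## Splits are always at the target level: a test target's entire candidate
## pool is held out, and inner CV for hyperparameters sees training targets
## only. Reported aggregates are means over test targets, with replicate
## standard errors over independent CV experiments.

#' Area under the ROC curve (pairwise ranking probability)
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' is scored higher than a randomly chosen negative, with ties counting 1/2.
#'
#' @param scores numeric scores (higher = more likely active).
#' @param labels binary 0/1 labels; at least one of each class required.
#' @return AUC in [0,1].
#' @examples
#' aucScore(c(3, 2, 1), c(1, 1, 0))  # 1
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop(validationError("scores and labels must have equal length"))
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  if (m == 0L || n == 0L)
    stop(validationError("undefined AUC: need both classes"))
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n)
}

#' Actives among the top N predicted
#'
#' Counts actives among the `N` highest-scored candidates using the
#' deterministic tie-break (descending score, then ascending id). When fewer
#' than `N` candidates exist, all are used.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels.
#' @param N size of the predicted short-list (default 10).
#' @param ids optional candidate ids for the tie-break (defaults to index).
#' @return list with `topN` (count of actives in the top N) and `hitN`
#'   (1 if `topN >= 1`).
#' @export
topN <- function(scores, labels, N = 10L, ids = NULL) {
  if (N < 1L) stop(validationError("N must be >= 1"))
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  ord <- order(-scores, ids)
  take <- head(ord, N)
  cnt <- sum(as.integer(labels)[take])
  list(topN = as.integer(cnt), hitN = as.integer(cnt >= 1L))
}

#' Expected %TopN of a random ranking (hypergeometric closed form)
#'
#' For a pool of `K` candidates with `m` actives, the probability that a
#' uniformly random ranking places at least one active in the top `N` is
#' `1 - choose(K - m, N) / choose(K, N)`.
#'
#' @param K pool size.
#' @param m number of actives.
#' @param N short-list size.
#' @return probability in [0,1].
#' @export
randomHitRate <- function(K, m, N = 10L) {
  ifelse(K - m < N, 1, 1 - exp(lchoose(K - m, N) - lchoose(K, N)))
}

## subset rows of a FeatureMatrix
subsetRows <- function(fm, rows) {
  new("FeatureMatrix", x = fm@x[rows, , drop = FALSE],
      columnData = fm@columnData, encoding = fm@encoding,
      rowTarget = fm@rowTarget[rows])
}

## Fit the requested learner directly on a prepared FeatureMatrix.
fitLearner <- function(fm, labels, learner, innerFolds, seed, lambdaGrid,
                       fingerprint, group) {
  switch(learner,
    lasso = fitLasso(fm, labels, lambdaGrid = lambdaGrid,
                     innerFolds = innerFolds, seed = seed,
                     fingerprint = fingerprint, group = group),
    gbm = fitGbm(fm, labels, innerFolds = innerFolds, seed = seed,
                 fingerprint = fingerprint, group = group),
    ensemble = fitEnsemble(list(
      fitLasso(fm, labels, lambdaGrid = lambdaGrid,
               innerFolds = innerFolds, seed = seed,
               fingerprint = fingerprint, group = group),
      fitGbm(fm, labels, innerFolds = innerFolds, seed = childSeed(seed, 1L),
             fingerprint = fingerprint, group = group))),
    stop(validationError(paste("unknown learner:", learner))))
}

## Score a prepared design (columns already aligned with the scorer).
scoreDesign <- function(scorer, fm) {
  if (scorer@kind == "ensemble") {
    S <- vapply(scorer@fit, scoreDesign, numeric(nrow(fm@x)), fm = fm)
    if (!is.matrix(S)) S <- matrix(S, nrow = 1L)
    if (scorer@combine == "score-mean") return(rowMeans(S))
    grp <- fm@rowTarget
    out <- numeric(nrow(S))
    for (g in unique(grp)) {
      i <- which(grp == g)
      out[i] <- rowMeans(apply(S[i, , drop = FALSE], 2L, fractionalRank))
    }
    return(out)
  }
  X <- fm@x
  if (scorer@kind == "lasso")
    as.numeric(predict(scorer@fit$glmnet, newx = X, s = scorer@fit$lambda,
                       type = "response"))
  else as.numeric(predict(scorer@fit, xgboost::xgb.DMatrix(X)))
}

## Evaluate ranked pools of a set of test targets; returns the per-target
## data.frame of a CVSummary.
evalPools <- function(records, scores, testTargets, N) {
  res <- lapply(testTargets, function(tt) {
    i <- which(records$target == tt)
    lab <- records$label[i]
    a <- if (length(unique(lab)) < 2L) NA_real_
         else aucScore(scores[i], lab)
    tn <- topN(scores[i], lab, N = N, ids = records$variant_id[i])
    data.frame(target = tt, n_candidates = length(i),
               n_positives = sum(lab), auc = a,
               topN = tn$topN, hitN = tn$hitN, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

## Prepare the full encoded matrix once; interactions unfiltered (support
## refiltered per replicate on training rows).
prepareDesign <- function(records, featureGroup, minSupport) {
  b1 <- encodeBin1(records)
  needs2 <- !featureGroup %in% c("Mact", "SM-5", "SM-11", "SM-5_11")
  if (needs2) addInteractions(b1, minSupport = 0L) else b1
}

#' Outer cross-validation at the target level
#'
#' Repeats a random target-level split (`testFraction` of targets held out,
#' their entire pools unseen during training), trains the requested learner
#' on the training pools with inner-CV hyperparameter selection, ranks every
#' test pool and reports per-target AUC / TopN / hitN plus aggregates with
#' replicate standard errors. Single-class test pools are excluded from AUC
#' averaging (with a per-target NA) but retained for TopN. The interaction
#' support filter is recomputed on each replicate's training rows.
#'
#' @param data ScreeningSet or records data.frame.
#' @param testFraction fraction of targets held out per replicate.
#' @param replicates number of independent CV experiments.
#' @param featureGroup feature group (see [featureGroups()]).
#' @param learner `"lasso"`, `"gbm"`, `"ensemble"`, or `"random"` (uniform
#'   random scores; calibration baseline).
#' @param minSupport interaction support threshold.
#' @param innerFolds inner CV folds.
#' @param seed master seed; replicate seeds are derived by fixed offsets so
#'   any replicate is reproducible in isolation.
#' @param N short-list size for TopN (default 10).
#' @param lambdaGrid optional lambda sequence for the LASSO member.
#' @return A [CVSummary-class].
#' @export
outerCv <- function(data, testFraction = 0.1, replicates = 30L,
                    featureGroup = "SeqMact", learner = "lasso",
                    minSupport = 200L, innerFolds = 3L, seed = 1L,
                    N = 10L, lambdaGrid = NULL) {
  rec <- recordsFrom(data)
  targets <- sort(unique(rec$target))
  nTest <- max(1L, as.integer(round(testFraction * length(targets))))
  if (nTest >= length(targets))
    stop(validationError("test split would leave no training targets"))
  fmAll <- if (learner == "random") NULL
           else prepareDesign(rec, featureGroup, minSupport)
  fp <- fingerprintRecords(rec)
  per <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    testT <- withSeed(childSeed(seed, r), sample(targets, nTest))
    trainRows <- which(!(rec$target %in% testT))
    testRows <- which(rec$target %in% testT)
    if (learner == "random") {
      scores <- withSeed(childSeed(seed, 5000L + r), runif(length(testRows)))
    } else {
      fm <- supportFilter(fmAll, trainRows, minSupport = minSupport)
      fm <- selectGroup(fm, featureGroup)
      scorer <- fitLearner(subsetRows(fm, trainRows), rec$label[trainRows],
                           learner, innerFolds, childSeed(seed, 1000L + r),
                           lambdaGrid, fp, featureGroup)
      scores <- scoreDesign(scorer, subsetRows(fm, testRows))
    }
    ev <- evalPools(rec[testRows, , drop = FALSE], scores, sort(testT), N)
    ev$replicate <- r
    per[[r]] <- ev
  }
  perTarget <- do.call(rbind, per)
  perTarget <- perTarget[c("replicate", setdiff(names(perTarget), "replicate"))]
  new("CVSummary", perTarget = perTarget,
      aggregates = cvAggregatesFrom(perTarget),
      settings = list(testFraction = testFraction, replicates = replicates,
                      featureGroup = featureGroup, learner = learner,
                      minSupport = minSupport, innerFolds = innerFolds,
                      seed = seed, N = N,
                      n_targets = length(targets), n_test = nTest,
                      n_train = length(targets) - nTest))
}

## replicate-level means and SEs
cvAggregatesFrom <- function(perTarget) {
  repMean <- function(col) {
    v <- tapply(perTarget[[col]], perTarget$replicate,
                function(x) mean(x, na.rm = TRUE))
    v <- v[!is.na(v)]
    list(mean = mean(v), se = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_)
  }
  a <- repMean("auc"); t <- repMean("topN"); h <- repMean("hitN")
  list(mean_auc = a$mean, se_auc = a$se,
       mean_topN = t$mean, se_topN = t$se,
       pct_topN = h$mean, se_pct_topN = h$se)
}

#' Learning curve over training-set size
#'
#' For each requested size, each replicate holds out the same test split as
#' [outerCv()] (same master seed, same derived replicate seeds), randomly
#' subsamples that many training targets, fits and evaluates on the fixed
#' test split. With `size` equal to the full training split the result
#' reproduces [outerCv()].
#'
#' @param data ScreeningSet or records data.frame.
#' @param trainSizes integer vector of training-target counts (each >= 1).
#' @param replicates replicates per size.
#' @inheritParams outerCv
#' @return data.frame: one row per (size, aggregate) with mean AUC/TopN/%TopN
#'   and SEs.
#' @export
learningCurve <- function(data, trainSizes, replicates = 10L,
                          testFraction = 0.1, featureGroup = "SeqMact",
                          learner = "lasso", minSupport = 200L,
                          innerFolds = 3L, seed = 1L, N = 10L,
                          lambdaGrid = NULL) {
  if (any(trainSizes < 1L))
    stop(validationError("training sizes must be >= 1"))
  rec <- recordsFrom(data)
  targets <- sort(unique(rec$target))
  nTest <- max(1L, round(testFraction * length(targets)))
  if (any(trainSizes > length(targets) - nTest))
    stop(validationError("training size exceeds available training targets"))
  fmAll <- prepareDesign(rec, featureGroup, minSupport)
  fp <- fingerprintRecords(rec)
  out <- list()
  for (size in trainSizes) {
    per <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      testT <- withSeed(childSeed(seed, r), sample(targets, nTest))
      trainT <- setdiff(targets, testT)
      if (size < length(trainT))
        trainT <- withSeed(childSeed(seed, 2000L + r),
                           sample(trainT, size))
      trainRows <- which(rec$target %in% trainT)
      testRows <- which(rec$target %in% testT)
      fm <- supportFilter(fmAll, trainRows, minSupport = minSupport)
      fm <- selectGroup(fm, featureGroup)
      scorer <- fitLearner(subsetRows(fm, trainRows), rec$label[trainRows],
                           learner, innerFolds, childSeed(seed, 1000L + r),
                           lambdaGrid, fp, featureGroup)
      scores <- scoreDesign(scorer, subsetRows(fm, testRows))
      ev <- evalPools(rec[testRows, , drop = FALSE], scores, sort(testT), N)
      ev$replicate <- r
      per[[r]] <- ev
    }
    agg <- cvAggregatesFrom(do.call(rbind, per))
    out[[length(out) + 1L]] <- data.frame(
      n_targets = size, mean_auc = agg$mean_auc, se_auc = agg$se_auc,
      mean_topN = agg$mean_topN, pct_topN = agg$pct_topN,
      se_pct_topN = agg$se_pct_topN)
  }
  do.call(rbind, out)
}

#' Distance-constrained training subsampling
#'
#' `mode = "distance"` keeps the training targets whose Hamming distance (on
#' the modeled half-site regions 11N4+5N3 by default) to every test target is
#' at least `minDist`; with all-distinct targets, `minDist = 1` keeps the
#' whole training split. `mode = "uniform"` randomly keeps the same number of
#' training targets (size-matched control).
#'
#' @param trainTargets,testTargets character vectors of 22-mers.
#' @param minDist minimum allowed distance (>= 1).
#' @param mode `"distance"` or `"uniform"`.
#' @param seed seed for the uniform control.
#' @param scope distance scope passed to [targetDistance()].
#' @return character vector of retained training targets, with attribute
#'   `retained_fraction`.
#' @export
distanceSubsample <- function(trainTargets, testTargets, minDist = 1L,
                              mode = c("distance", "uniform"), seed = 1L,
                              scope = c("r11N4", "r5N3")) {
  mode <- match.arg(mode)
  if (minDist < 1L) stop(validationError("minDist must be >= 1"))
  minD <- vapply(trainTargets, function(tr)
    min(targetDistance(rep(tr, length(testTargets)), testTargets,
                       scope = scope)), 0L)
  keepDist <- trainTargets[minD >= minDist]
  if (!length(keepDist))
    stop(validationError(
      "no training targets at the requested distance; lower minDist"))
  kept <- if (mode == "distance") keepDist
          else withSeed(childSeed(seed, 3000L),
                        sample(trainTargets, length(keepDist)))
  attr(kept, "retained_fraction") <- length(keepDist) / length(trainTargets)
  kept
}
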