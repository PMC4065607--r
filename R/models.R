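## Learners and the ensemble scorer.
##
## Training is binary classification (active / inactive): the screening data
## record activity scores only for sequenced positives, so the continuous
## score is not a usable regression response. The linear member is an
## L1-penalized logistic model (glmnet) on the binary encodings; the tree
## member is a gradient-boosted decision-tree classifier (xgboost, binomial
## loss) trained on the one-hot representation of the categorical dataset.
## Hyperparameters come from inner cross-validation on the training fold
## only; the ensemble averages per-pool fractional ranks of its members.

## Cheap stable fingerprint of a record table, used to guard against
## combining scorers trained on different data.
fingerprintRecords <- function(records) {
  ids <- paste0(records$target, records$variant_id)
  h <- sum((seq_along(ids) %% 97 + 1) *
             vapply(ids, function(s) sum(utf8ToInt(s)), 0)) %% 2147483647
  sprintf("n%d-p%d-h%.0f", nrow(records), sum(records$label), h)
}

asDesign <- function(fm) {
  if (is.data.frame(fm@x))
    stop(validationError("learner needs a bin1/bin2 matrix; encode first"))
  fm@x
}

checkLabels <- function(labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop(validationError("degenerate labels: need both classes to train"))
  labels
}

encoderOf <- function(fm) list(columnData = fm@columnData,
                               encoding = fm@encoding)

#' Fit the L1-penalized logistic (LASSO) member
#'
#' Penalty strength is chosen to maximize inner-cross-validation AUC over the
#' lambda path (deviance is used instead when folds are too small for a
#' stable AUC estimate). Coefficients at the selected penalty are exportable
#' with feature names via [coefTable()].
#'
#' @param fm Bin1/Bin2 [FeatureMatrix-class] of the training records.
#' @param labels binary 0/1 labels.
#' @param lambdaGrid optional explicit lambda sequence; default lets glmnet
#'   build a 30-value path.
#' @param innerFolds number of inner CV folds.
#' @param seed integer seed controlling fold assignment.
#' @param fingerprint optional training-data fingerprint to store.
#' @param group feature-group name stored on the scorer.
#' @return A [TrainedScorer-class] of kind `"lasso"`.
#' @export
fitLasso <- function(fm, labels, lambdaGrid = NULL, innerFolds = 5L,
                     seed = 1L, fingerprint = "", group = "SeqMact") {
  X <- asDesign(fm)
  y <- checkLabels(labels)
  if (nrow(X) != length(y))
    stop(validationError("labels must match design-matrix rows"))
  foldid <- withSeed(seed, sample(rep_len(seq_len(innerFolds), length(y))))
  measure <- if (min(table(y)) >= 8L * innerFolds && length(y) >= 60L)
    "auc" else "deviance"
  args <- list(x = X, y = y, family = "binomial", type.measure = measure,
               foldid = foldid, standardize = FALSE, thresh = 1e-5)
  if (!is.null(lambdaGrid)) args$lambda <- sort(lambdaGrid, decreasing = TRUE)
  else { args$nlambda <- 12L; args$lambda.min.ratio <- 0.05 }
  cvfit <- do.call(glmnet::cv.glmnet, args)
  new("TrainedScorer", kind = "lasso",
      fit = list(glmnet = cvfit$glmnet.fit, lambda = cvfit$lambda.min),
      featureGroup = group, encoder = encoderOf(fm),
      innerCV = list(measure = measure, lambda = cvfit$lambda,
                     cvm = cvfit$cvm, chosen = cvfit$lambda.min,
                     folds = innerFolds, seed = seed),
      fingerprint = fingerprint)
}

#' Coefficients of a fitted LASSO scorer
#'
#' @param scorer a `"lasso"` [TrainedScorer-class].
#' @return data.frame (`feature`, `coef`) at the selected penalty, intercept
#'   included as `(Intercept)`.
#' @export
coefTable <- function(scorer) {
  stopifnot(is(scorer, "TrainedScorer"))
  if (scorer@kind != "lasso") stop("coefTable is defined for lasso scorers")
  b <- as.matrix(predict(scorer@fit$glmnet, s = scorer@fit$lambda,
                         type = "coefficients"))
  data.frame(feature = rownames(b), coef = b[, 1L], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fit the gradient-boosted-tree member
#'
#' Boosted decision-tree classifier with binomial (logistic) loss. Tree depth
#' and the number of boosting rounds are selected by inner cross-validation
#' AUC with early stopping; the learning rate is fixed by the grid.
#'
#' @param fm Bin1/Bin2 [FeatureMatrix-class] (one-hot representation of the
#'   categorical dataset).
#' @param labels binary 0/1 labels.
#' @param paramGrid data.frame of candidate settings with columns `max_depth`
#'   and `eta`.
#' @param nrounds maximum boosting rounds (early stopping inside CV).
#' @param innerFolds inner CV folds.
#' @param seed integer seed; single-threaded training keeps predictions
#'   bit-identical across reruns.
#' @param fingerprint,group metadata stored on the scorer.
#' @return A [TrainedScorer-class] of kind `"gbm"`.
#' @export
fitGbm <- function(fm, labels,
                   paramGrid = data.frame(max_depth = c(2L, 4L), eta = 0.1),
                   nrounds = 150L, innerFolds = 3L, seed = 1L,
                   fingerprint = "", group = "SeqMact") {
  X <- asDesign(fm)
  y <- checkLabels(labels)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  best <- NULL
  cvlog <- list()
  for (g in seq_len(nrow(paramGrid))) {
    params <- list(objective = "binary:logistic", eval_metric = "auc",
                   max_depth = paramGrid$max_depth[g],
                   eta = paramGrid$eta[g], nthread = 1L)
    cv <- withSeed(seed, xgboost::xgb.cv(
      params = params, data = dtrain, nrounds = nrounds,
      nfold = innerFolds, early_stopping_rounds = 15L, verbose = 0L))
    log <- as.data.frame(cv$evaluation_log)
    it <- which.max(log$test_auc_mean)
    auc <- log$test_auc_mean[it]
    cvlog[[g]] <- list(params = params, best_iteration = it, cv_auc = auc)
    if (is.null(best) || auc > best$cv_auc)
      best <- list(params = params, nrounds = it, cv_auc = auc)
  }
  fit <- withSeed(seed, xgboost::xgb.train(
    params = best$params, data = dtrain, nrounds = best$nrounds,
    verbose = 0L))
  new("TrainedScorer", kind = "gbm", fit = fit, featureGroup = group,
      encoder = encoderOf(fm),
      innerCV = list(measure = "auc", grid = paramGrid, log = cvlog,
                     chosen = best, folds = innerFolds, seed = seed),
      fingerprint = fingerprint)
}

#' Feature importances of a fitted boosted-tree scorer
#'
#' @param scorer a `"gbm"` [TrainedScorer-class].
#' @return data.frame of xgboost gain-based importances.
#' @export
importanceTable <- function(scorer) {
  stopifnot(is(scorer, "TrainedScorer"))
  if (scorer@kind != "gbm") stop("importanceTable is defined for gbm scorers")
  as.data.frame(xgboost::xgb.importance(model = scorer@fit))
}

#' Model-estimated epistasis between two residues
#'
#' Quantifies the interaction a fitted scorer attributes to the simultaneous
#' presence of `res1` at `pos1` and `res2` at `pos2` as a
#' difference-in-differences of predicted log-odds over counterfactual
#' variants: records carrying both residues are re-encoded with each residue
#' reverted to the wild type, and the second difference
#' `[s(r1,r2) - s(r1,wt2)] - [s(wt1,r2) - s(wt1,wt2)]` is averaged. Unlike a
#' single product-column coefficient, this contrast is invariant to how a
#' sparse fit distributes weight across collinear encodings of the same
#' variants, and main effects and residue-target terms cancel in the second
#' difference.
#'
#' @param scorer a `"lasso"` or `"gbm"` [TrainedScorer-class].
#' @param x ScreeningSet or records data.frame to draw carrier records from.
#' @param pos1,pos2 interface positions (e.g. 44 and 77).
#' @param res1,res2 the residue pair of interest.
#' @param maxRecords cap on carrier records used (default 500).
#' @return mean log-odds difference-in-differences (negative = deleterious
#'   pair), or NA if no record carries the pair.
#' @export
epistasisContrast <- function(scorer, x, pos1, res1, pos2, res2,
                              maxRecords = 500L) {
  rec <- recordsFrom(x)
  c1 <- paste0("p", pos1); c2 <- paste0("p", pos2)
  carriers <- rec[rec[[c1]] == res1 & rec[[c2]] == res2, , drop = FALSE]
  if (!nrow(carriers)) return(NA_real_)
  carriers <- head(carriers, maxRecords)
  wt1 <- WT_RESIDUES[[as.character(pos1)]]
  wt2 <- WT_RESIDUES[[as.character(pos2)]]
  variants <- list(
    rr = carriers,
    rw = transform2(carriers, c2, wt2),
    wr = transform2(carriers, c1, wt1),
    ww = transform2(transform2(carriers, c1, wt1), c2, wt2))
  s <- lapply(variants, function(v) {
    p <- predictActivity(scorer, v)
    qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  })
  mean((s$rr - s$rw) - (s$wr - s$ww))
}

transform2 <- function(rec, col, val) { rec[[col]] <- val; rec }

#' Combine member scorers into a rank ensemble
#'
#' The ensemble score of a candidate is the unweighted mean of the members'
#' per-pool fractional ranks: within every candidate pool (records sharing a
#' target) each member's raw scores are mapped to [0,1] by fractional rank,
#' making the ensemble invariant under strictly monotone transforms of any
#' member's scores. A single member yields the identity. `combine =
#' "score-mean"` averages raw scores instead (config variant).
#'
#' @param members list of [TrainedScorer-class] objects trained on the same
#'   records (fingerprints must agree).
#' @param combine `"rank-mean"` (default) or `"score-mean"`.
#' @return A [TrainedScorer-class] of kind `"ensemble"`.
#' @export
fitEnsemble <- function(members, combine = c("rank-mean", "score-mean")) {
  combine <- match.arg(combine)
  if (!length(members)) stop(validationError("ensemble needs >= 1 member"))
  stopifnot(all(vapply(members, is, TRUE, "TrainedScorer")))
  fps <- unique(vapply(members, function(m) m@fingerprint, ""))
  if (length(fps) > 1L)
    stop(validationError(
      "fingerprint mismatch: members were trained on different records"))
  new("TrainedScorer", kind = "ensemble", fit = members,
      featureGroup = paste(unique(vapply(members, scorerGroup, "")),
                           collapse = "+"),
      encoder = list(), innerCV = list(), fingerprint = fps,
      combine = combine)
}

## fractional rank in (0, 1]: average rank / n, ties averaged
fractionalRank <- function(x) rank(x, ties.method = "average") / length(x)

#' Predict activity scores for screening records
#'
#' Returns one real-valued score per record; higher means more likely active.
#' Ensemble scores are per-pool fractional-rank means of the members'
#' scores (pools are groups of records sharing a target).
#'
#' @param scorer a [TrainedScorer-class].
#' @param x ScreeningSet or records data.frame (residues, regions and module
#'   activities present; labels not required).
#' @return numeric score vector aligned with the rows of `x`.
#' @export
predictActivity <- function(scorer, x) {
  stopifnot(is(scorer, "TrainedScorer"))
  rec <- recordsFrom(x)
  if (scorer@kind == "ensemble") {
    S <- vapply(scorer@fit, predictActivity, numeric(nrow(rec)), x = rec)
    if (!is.matrix(S)) S <- matrix(S, nrow = 1L)
    if (scorer@combine == "score-mean") return(rowMeans(S))
    grp <- as.character(rec$target)
    out <- numeric(nrow(rec))
    for (g in unique(grp)) {
      i <- which(grp == g)
      out[i] <- rowMeans(apply(S[i, , drop = FALSE], 2L, fractionalRank))
    }
    return(out)
  }
  template <- scorer@encoder
  fm <- encodeLike(rec, new("FeatureMatrix",
                            x = Matrix::Matrix(0, 0, nrow(template$columnData),
                                               sparse = TRUE),
                            columnData = template$columnData,
                            encoding = template$encoding,
                            rowTarget = character()))
  X <- fm@x
  if (scorer@kind == "lasso")
    as.numeric(predict(scorer@fit$glmnet, newx = X, s = scorer@fit$lambda,
                       type = "response"))
  else if (scorer@kind == "gbm")
    as.numeric(predict(scorer@fit, xgboost::xgb.DMatrix(X)))
  else stop("unknown scorer kind: ", scorer@kind)
}

#' Rank candidate variants for a target
#'
#' Orders records by descending predicted score with a deterministic
#' tie-break (lexicographic on `variant_id`), so rankings are reproducible
#' and independent of input order. Records that cannot be encoded raise a
#' validation error rather than being dropped silently.
#'
#' @param scorer a [TrainedScorer-class].
#' @param x ScreeningSet or records data.frame (typically one target's pool).
#' @return records data.frame with a `score` column, ordered best-first.
#' @export
rankCandidates <- function(scorer, x) {
  rec <- recordsFrom(x)
  rec$score <- predictActivity(scorer, rec)
  ord <- order(-rec$score, rec$variant_id)
  out <- rec[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build prediction records for candidates on a target
#'
#' Assembles the record table [predictActivity()] expects from a candidate
#' table and the module libraries (module-activity lookup for the Mact
#' columns).
#'
#' @param target 22-base target string.
#' @param candidates data.frame with `variant_id`, `p5_module`, `p11_module`
#'   and residue columns (e.g. [poolCandidates()]).
#' @param p5Lib,p11Lib ModuleLibrary objects for the activity lookup.
#' @return records data.frame ready for scoring.
#' @export
buildRecords <- function(target, candidates, p5Lib, p11Lib) {
  target <- assertDna(target, 22L)
  regs <- extractRegions(target)
  rec <- candidates
  rec$target <- target
  rec$r5N3 <- regs$r5N3
  rec$r11N4 <- regs$r11N4
  joinModuleActivities(rec, p5Lib, p11Lib)
}

#' Train a ranking scorer on screening data
#'
#' End-to-end training convenience: encodes the records (Bin1, plus
#' interaction products when the feature group requires them), restricts to
#' the requested group, fits the requested learner(s) with inner-CV
#' hyperparameter selection and returns the scorer (an ensemble of LASSO and
#' GBM by default).
#'
#' @param x ScreeningSet or records data.frame with labels.
#' @param group feature-group name (see [featureGroups()]).
#' @param learner `"ensemble"` (LASSO + GBM), `"lasso"` or `"gbm"`.
#' @param minSupport interaction support threshold (see [addInteractions()]).
#' @param innerFolds inner CV folds.
#' @param seed integer seed.
#' @param lambdaGrid optional lambda sequence for the LASSO member.
#' @param combine ensemble combination rule.
#' @return A [TrainedScorer-class].
#' @export
trainScorer <- function(x, group = "SeqMact",
                        learner = c("ensemble", "lasso", "gbm"),
                        minSupport = 200L, innerFolds = 3L, seed = 1L,
                        lambdaGrid = NULL,
                        combine = c("rank-mean", "score-mean")) {
  learner <- match.arg(learner)
  combine <- match.arg(combine)
  rec <- recordsFrom(x)
  fp <- fingerprintRecords(rec)
  b1 <- encodeBin1(rec)
  needs2 <- !group %in% c("Mact", "SM-5", "SM-11", "SM-5_11")
  fm <- if (needs2) addInteractions(b1, minSupport = minSupport) else b1
  fm <- selectGroup(fm, group)
  y <- rec$label
  members <- list()
  if (learner %in% c("ensemble", "lasso"))
    members <- c(members, list(
      fitLasso(fm, y, lambdaGrid = lambdaGrid, innerFolds = innerFolds,
               seed = seed, fingerprint = fp, group = group)))
  if (learner %in% c("ensemble", "gbm"))
    members <- c(members, list(
      fitGbm(fm, y, innerFolds = innerFolds, seed = childSeed(seed, 1L),
             fingerprint = fp, group = group)))
  if (length(members) == 1L) members[[1L]]
  else fitEnsemble(members, combine = combine)
}
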