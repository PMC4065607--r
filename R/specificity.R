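## Specificity profiles and the activity/specificity trade-off.
##
## The specificity of mutant p on target t is its activity on t divided by
## its total activity over the whole target space (here, the 64 5N3 targets
## by default), so each mutant's specificity profile sums to 1. Candidates
## are ranked by R_alpha = alpha * A + (1 - alpha) * S, where A is the
## predicted activity (min-max rescaled across the candidate pool so the two
## terms share a [0,1] scale) and S the predicted specificity on the target
## of interest.

#' Specificity profiles from an activity matrix
#'
#' Row-normalizes a mutant x target activity matrix: S[p, t] = A[p, t] /
#' sum_t A[p, t]. Mutants with zero total activity have an undefined profile
#' (NA row, flagged in the `undefined` attribute) and are excluded from
#' specificity-based rankings.
#'
#' @param activities nonnegative numeric matrix, mutants in rows.
#' @return matrix of the same shape whose rows sum to 1 (or are NA), with
#'   attribute `undefined` (logical per row).
#' @export
specificityProfile <- function(activities) {
  if (any(activities < 0, na.rm = TRUE))
    stop(validationError("activities must be nonnegative"))
  tot <- rowSums(activities)
  S <- activities / tot
  undef <- tot == 0
  S[undef, ] <- NA_real_
  attr(S, "undefined") <- undef
  S
}

#' Rank candidates by the activity/specificity trade-off
#'
#' Computes `R_alpha = alpha * A' + (1 - alpha) * S` where `A'` is the
#' min-max rescaling of `A` across the candidates (constant `A` rescales to
#' 0), and orders candidates by descending `R_alpha` with a deterministic
#' tie-break on candidate names. `alpha = 1` reproduces the pure activity
#' ranking, `alpha = 0` the pure specificity ranking.
#'
#' @param A numeric vector of predicted activities on the target of interest.
#' @param S numeric vector of predicted specificities there (aligned to `A`).
#' @param alpha trade-off weight in [0,1].
#' @param ids optional candidate ids (default: names of `A`, else index).
#' @param rescale min-max rescale `A` across candidates before mixing
#'   (default TRUE, so alpha weighs two quantities on a common [0,1] scale);
#'   FALSE mixes the raw values.
#' @return data.frame (`id`, `A`, `S`, `R`) ordered best-first.
#' @export
tradeoffRank <- function(A, S, alpha, ids = NULL, rescale = TRUE) {
  if (length(A) != length(S))
    stop(validationError("A and S must be aligned"))
  if (alpha < 0 || alpha > 1) stop(validationError("alpha must be in [0,1]"))
  if (is.null(ids)) ids <- if (!is.null(names(A))) names(A)
                           else as.character(seq_along(A))
  Ar <- A
  if (rescale) {
    rng <- range(A, finite = TRUE)
    Ar <- if (diff(rng) > 0) (A - rng[1L]) / diff(rng) else rep(0, length(A))
  }
  R <- alpha * Ar + (1 - alpha) * S
  ord <- order(-R, ids)
  data.frame(id = ids[ord], A = A[ord], S = S[ord], R = R[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Count active, sufficiently specific candidates in the top N
#'
#' Among the `N` best-ranked candidates, counts those that are truly active
#' and whose true specificity is at least the reference threshold (the
#' wild-type's specificity on its cognate target within the same target
#' space).
#'
#' @param ranked data.frame from [tradeoffRank()] (or any table with an `id`
#'   column, best-first).
#' @param activeLabels named binary vector of true activity labels.
#' @param trueS named numeric vector of true specificities on the target of
#'   interest.
#' @param threshold specificity threshold (wild-type reference).
#' @param N short-list size (default 10).
#' @return integer count.
#' @export
countSpecificActives <- function(ranked, activeLabels, trueS, threshold,
                                 N = 10L) {
  ids <- head(ranked$id, N)
  sum(activeLabels[ids] >= 1 & trueS[ids] >= threshold, na.rm = TRUE)
}

#' Predicted activity and specificity of candidates over the 5N3 space
#'
#' Predicts each candidate's activity (probability scale) on all 64 variants
#' of the target obtained by enumerating the 5N3 region (11N4 held fixed),
#' and derives the predicted specificity on the target of interest as the
#' row-normalized share. Prediction over the enumerated space is fast, so
#' specificity screening of a whole candidate list is routine.
#'
#' @param scorer a [TrainedScorer-class].
#' @param target 22-base target of interest.
#' @param candidates candidate data.frame (`variant_id`, modules, residues).
#' @param p5Lib,p11Lib ModuleLibrary objects for module-activity lookups.
#' @return data.frame (`variant_id`, `A` = predicted activity on the target,
#'   `S` = predicted specificity there), plus the full prediction matrix in
#'   attribute `matrix`.
#' @export
predictSpecificity <- function(scorer, target, candidates, p5Lib, p11Lib) {
  target <- assertDna(target, 22L)
  regs <- extractRegions(target)
  space <- enumerateRegionSpace("5N3")
  allRec <- do.call(rbind, lapply(space, function(s5) {
    t2 <- targetFromRegions(s5, regs$r11N4, regs$r7N2)
    buildRecords(t2, candidates, p5Lib, p11Lib)
  }))
  scores <- predictActivity(scorer, allRec)
  M <- matrix(scores, nrow = nrow(candidates), ncol = length(space),
              dimnames = list(candidates$variant_id, space))
  S <- specificityProfile(M)
  j <- match(regs$r5N3, space)
  out <- data.frame(variant_id = candidates$variant_id,
                    A = M[, j], S = S[, j], stringsAsFactors = FALSE)
  attr(out, "matrix") <- M
  out
}

#' Sweep the trade-off weight alpha
#'
#' For each target in the target space and each alpha, ranks all mutants by
#' `R_alpha` computed from the predicted activity matrix and counts active
#' mutants at least as specific as the reference in the top `N`; returns the
#' per-alpha average over targets. With activity and specificity
#' anticorrelated across mutants, the curve is low at both endpoints and
#' peaks at intermediate alpha.
#'
#' @param predicted mutant x target predicted activity matrix.
#' @param truth mutant x target true activity matrix (labels thresholded at
#'   `tau`).
#' @param alphas numeric vector of trade-off weights.
#' @param threshold specificity threshold (e.g. the wild type's specificity
#'   on its cognate target).
#' @param tau activity threshold defining true actives.
#' @param N short-list size.
#' @return data.frame (`alpha`, `mean_count`).
#' @export
alphaSweep <- function(predicted, truth, alphas, threshold, tau = 0.25,
                       N = 10L) {
  if (!identical(dim(predicted), dim(truth)))
    stop(validationError("predicted and truth must have identical shape"))
  Spred <- specificityProfile(predicted)
  Strue <- specificityProfile(truth)
  ids <- rownames(predicted)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(predicted)))
  res <- vapply(alphas, function(al) {
    counts <- vapply(seq_len(ncol(predicted)), function(j) {
      labels <- setNames(as.integer(truth[, j] >= tau), ids)
      sj <- setNames(Strue[, j], ids)
      rk <- tradeoffRank(setNames(predicted[, j], ids),
                         Spred[, j], al, ids = ids)
      countSpecificActives(rk, labels, sj, threshold, N = N)
    }, 0L)
    mean(counts)
  }, 0)
  data.frame(alpha = alphas, mean_count = res)
}
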