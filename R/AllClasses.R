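## Central S4 containers.

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' ModuleLibrary: building modules of one interface half and their activities
#'
#' A module library holds half-variants mutated at the interface positions of
#' one module side (p5N3: 44,68,70,75,77; p11N4: 30,32,33,38,40) together with
#' their measured cleavage activity on every target of the corresponding
#' region space (64 5N3 or 256 11N4 targets). Simulated libraries additionally
#' carry the latent (noise-free) compatibility matrix used as ground truth.
#'
#' @slot region `"p5N3"` or `"p11N4"`.
#' @slot modules data.frame: `module_id` plus one residue column per key
#'   position of the side (e.g. `p44`, `p68`, ...).
#' @slot activities numeric matrix modules x region targets, values in [0,1];
#'   rownames are module ids, colnames the enumerated region space.
#' @slot latent optional noise-free compatibility matrix of the same shape
#'   (simulated libraries only).
#' @export
setClass("ModuleLibrary",
  representation(region = "character", modules = "data.frame",
                 activities = "matrix", latent = "matrixOrNULL"),
  prototype(latent = NULL))

setValidity("ModuleLibrary", function(object) {
  msgs <- character()
  if (!object@region %in% c("p5N3", "p11N4"))
    msgs <- c(msgs, "region must be 'p5N3' or 'p11N4'")
  else {
    pos <- if (object@region == "p5N3") P5N3_POSITIONS else P11N4_POSITIONS
    want <- paste0("p", pos)
    if (!all(c("module_id", want) %in% names(object@modules)))
      msgs <- c(msgs, paste("modules must have columns module_id,",
                            paste(want, collapse = ", ")))
    space <- enumerateRegionSpace(sub("^p", "", object@region))
    if (!identical(colnames(object@activities), space))
      msgs <- c(msgs, "activity colnames must be the enumerated region space")
  }
  if (!identical(rownames(object@activities),
                 as.character(object@modules$module_id)))
    msgs <- c(msgs, "activity rownames must match module ids")
  if (any(object@activities < 0 | object@activities > 1))
    msgs <- c(msgs, "activities must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' CombinatorialPool: assembled candidates screened against one target
#'
#' @slot target 22-base pseudopalindromic target string.
#' @slot candidates data.frame of assembled full variants: `variant_id`,
#'   `p5_module`, `p11_module` and the ten residue columns `p30` ... `p77`.
#' @slot positives data.frame (`variant_id`, `activity`) of sequenced positive
#'   variants; a subset of the candidates.
#' @slot provenance list: module ids used per side, oversampling factor, seed.
#' @export
setClass("CombinatorialPool",
  representation(target = "character", candidates = "data.frame",
                 positives = "data.frame", provenance = "list"))

setValidity("CombinatorialPool", function(object) {
  msgs <- character()
  if (length(object@target) != 1L || nchar(object@target) != 22L)
    msgs <- c(msgs, "target must be a single 22-base string")
  need <- c("variant_id", "p5_module", "p11_module",
            paste0("p", KEY_POSITIONS))
  if (!all(need %in% names(object@candidates)))
    msgs <- c(msgs, "candidates lack required columns")
  if (nrow(object@positives) &&
      !all(object@positives$variant_id %in% object@candidates$variant_id))
    msgs <- c(msgs, "positives must be a subset of candidates")
  if (anyDuplicated(object@candidates$variant_id))
    msgs <- c(msgs, "candidate variant ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' ScreeningSet: labeled screening records across targets
#'
#' Flat record table of the combinatorial screen: one row per (variant,
#' target) candidate with its module provenance, residues, module activities
#' on the target's regions, activity score, binary label and a measured flag
#' (FALSE for assumed negatives under positive-only sequencing).
#'
#' @slot records data.frame, one row per screening record.
#' @slot targets character vector of distinct target 22-mers.
#' @slot meta list of generation metadata (seed, calibration parameters, ...).
#' @export
setClass("ScreeningSet",
  representation(records = "data.frame", targets = "character", meta = "list"))

SCREENING_COLUMNS <- c("target", "r5N3", "r11N4", "variant_id",
                       "p5_module", "p11_module", paste0("p", KEY_POSITIONS),
                       "act5", "act11", "activity", "label", "measured")

setValidity("ScreeningSet", function(object) {
  msgs <- character()
  if (!all(SCREENING_COLUMNS %in% names(object@records)))
    msgs <- c(msgs, paste("records must have columns:",
                          paste(setdiff(SCREENING_COLUMNS,
                                        names(object@records)), collapse = ", ")))
  else {
    if (!all(object@records$target %in% object@targets))
      msgs <- c(msgs, "record targets missing from target list")
    if (!all(object@records$label %in% c(0L, 1L)))
      msgs <- c(msgs, "label must be 0/1")
    act <- object@records$activity
    if (any(act < 0 | act > 1, na.rm = TRUE))
      msgs <- c(msgs, "activity must lie in [0,1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' FeatureMatrix: encoded design matrix with per-column group metadata
#'
#' @slot x the design matrix: a data.frame of factors and numerics for the
#'   categorical encoding, or a sparse `Matrix` for Bin1/Bin2.
#' @slot columnData data.frame describing every column: `name`, `source`
#'   (protein_seq/target_seq/module_activity/interaction), `position`,
#'   `level`, `module_side` (p5N3/p11N4/cross/none), `order` (1/2),
#'   `parent1`, `parent2`, `iclass` (M2M/M2T/T2T/none).
#' @slot encoding `"categorical"`, `"bin1"` or `"bin2"`.
#' @slot rowTarget character vector: target of each row (for per-pool
#'   grouping).
#' @export
setClass("FeatureMatrix",
  representation(x = "ANY", columnData = "data.frame", encoding = "character",
                 rowTarget = "character"))

setValidity("FeatureMatrix", function(object) {
  msgs <- character()
  need <- c("name", "source", "position", "level", "module_side", "order",
            "parent1", "parent2", "iclass")
  if (!all(need %in% names(object@columnData)))
    msgs <- c(msgs, "columnData lacks required columns")
  ncols <- if (is.data.frame(object@x)) ncol(object@x) else ncol(object@x)
  if (nrow(object@columnData) != ncols)
    msgs <- c(msgs, "columnData rows must match matrix columns")
  if (!object@encoding %in% c("categorical", "bin1", "bin2"))
    msgs <- c(msgs, "unknown encoding")
  n <- if (is.data.frame(object@x)) nrow(object@x) else nrow(object@x)
  if (length(object@rowTarget) != n)
    msgs <- c(msgs, "rowTarget must match row count")
  o2 <- object@columnData$order == 2L
  if (any(o2) && any(is.na(object@columnData$parent1[o2])))
    msgs <- c(msgs, "order-2 columns need two parents")
  if (length(msgs)) msgs else TRUE
})

#' TrainedScorer: a fitted ranking model for candidate variants
#'
#' @slot kind `"lasso"`, `"gbm"` or `"ensemble"`.
#' @slot fit fitted model object (glmnet/xgboost), or list of member scorers
#'   for an ensemble.
#' @slot featureGroup name of the feature group the scorer was trained on.
#' @slot encoder encoding specification (levels per column, retained
#'   interaction pairs) used to rebuild prediction matrices.
#' @slot innerCV list recording grids, fold scores and chosen values.
#' @slot fingerprint character fingerprint of the training records.
#' @slot combine ensemble combination rule (`"rank-mean"` or `"score-mean"`).
#' @export
setClass("TrainedScorer",
  representation(kind = "character", fit = "ANY", featureGroup = "character",
                 encoder = "list", innerCV = "list", fingerprint = "character",
                 combine = "character"),
  prototype(combine = "rank-mean"))

#' GroundTruthModel: generative model behind the synthetic screen
#'
#' Additive latent-scale activity model: module compatibilities on the two
#' region spaces, plus non-specific per-residue effects, protein-protein
#' (M2M) pair effects, protein-target (M2T) residue-nucleotide effects and
#' Gaussian noise, squashed into [0,1]. Labels threshold the score at
#' `tau_active`; scores at or above 0.8 are "strong".
#'
#' @slot p5 ModuleLibrary of the p5N3 side (with latent compatibilities).
#' @slot p11 ModuleLibrary of the p11N4 side.
#' @slot params list: `b0`, `w5`, `w11`, `sigma`, `tau_active`, `strong`.
#' @slot nonspecific data.frame (`position`, `residue`, `effect`).
#' @slot m2m data.frame (`pos1`, `res1`, `pos2`, `res2`, `effect`).
#' @slot m2t data.frame (`position`, `residue`, `region`, `index`, `nt`,
#'   `effect`): residue-nucleotide preferences at contacting position pairs.
#' @slot seed integer seed the model was built from.
#' @export
setClass("GroundTruthModel",
  representation(p5 = "ModuleLibrary", p11 = "ModuleLibrary", params = "list",
                 nonspecific = "data.frame", m2m = "data.frame",
                 m2t = "data.frame", seed = "integer"))

#' CVSummary: per-target cross-validation evaluations and aggregates
#'
#' @slot perTarget data.frame: `replicate`, `target`, `n_candidates`,
#'   `n_positives`, `auc`, `topN`, `hitN` (auc is NA for single-class pools,
#'   which are excluded from AUC averaging but kept for TopN).
#' @slot aggregates list: `mean_auc`, `mean_topN`, `pct_topN` and their
#'   replicate standard errors.
#' @slot settings list of protocol settings (fractions, replicates, group,
#'   learner, seeds, N).
#' @export
setClass("CVSummary",
  representation(perTarget = "data.frame", aggregates = "list",
                 settings = "list"))

setValidity("CVSummary", function(object) {
  need <- c("replicate", "target", "n_candidates", "n_positives",
            "auc", "topN", "hitN")
  if (!all(need %in% names(object@perTarget)))
    return("perTarget lacks required columns")
  bad <- with(object@perTarget, hitN != (topN >= 1L))
  if (any(bad)) return("hitN must equal (topN >= 1)")
  TRUE
})
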