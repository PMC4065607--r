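## Combinatorial screening process: module assembly, coverage, labeling.

#' Expected coverage of combination space under oversampled random assembly
#'
#' When `N` module combinations are sampled uniformly with replacement
#' `k * N` times (oversampling factor `k`), the expected fraction of distinct
#' combinations observed is `1 - (1 - 1/N)^(k*N)`, which converges to
#' `1 - exp(-k)` for large `N`. At the screening scale of 40 x 40 modules
#' (N = 1600) and triple oversampling this is about 95%.
#'
#' @param nCombinations number of possible module combinations (>= 1).
#' @param oversampling nonnegative oversampling factor `k`.
#' @return expected covered fraction in [0,1].
#' @examples
#' expectedCoverage(1600, 3)  # ~0.9503
#' @export
expectedCoverage <- function(nCombinations, oversampling) {
  if (any(nCombinations < 1)) stop("nCombinations must be >= 1", call. = FALSE)
  if (any(oversampling < 0)) stop("oversampling must be >= 0", call. = FALSE)
  1 - (1 - 1 / nCombinations)^(oversampling * nCombinations)
}

## Normalize a module argument: accept a ModuleLibrary (all modules) or a
## modules data.frame (module_id + residue columns).
moduleFrame <- function(x, region) {
  if (is(x, "ModuleLibrary")) {
    if (moduleRegion(x) != region)
      stop("module library has wrong region: ", moduleRegion(x), call. = FALSE)
    return(moduleResidues(x))
  }
  if (is.data.frame(x)) return(x)
  stop("modules must be a ModuleLibrary or data.frame", call. = FALSE)
}

#' Assemble a combinatorial candidate pool for one target
#'
#' Emulates random PCR assembly of full variants from the two module sets:
#' `ceiling(oversampling * |p5| * |p11|)` module pairs are drawn uniformly
#' with replacement and deduplicated. The sampling unit is the module pair,
#' matching the combination-level diversity arithmetic of the screening
#' process.
#'
#' @param target 22-base target the pool is screened against.
#' @param p5Modules,p11Modules ModuleLibrary objects or data.frames
#'   (`module_id` + residue columns) giving the module sets used for assembly.
#' @param oversampling sampling factor relative to the theoretical diversity.
#' @param seed integer seed; assembly is reproducible given the seed.
#' @return A [CombinatorialPool-class] with deduplicated candidates and empty
#'   positives (screening fills those in).
#' @export
assemblePool <- function(target, p5Modules, p11Modules, oversampling = 3,
                         seed = 1L) {
  target <- assertDna(target, 22L)
  m5 <- moduleFrame(p5Modules, "p5N3")
  m11 <- moduleFrame(p11Modules, "p11N4")
  if (!nrow(m5) || !nrow(m11)) stop("empty module set", call. = FALSE)
  n5 <- nrow(m5); n11 <- nrow(m11)
  nDraw <- ceiling(oversampling * n5 * n11)
  rng <- withSeed(seed, {
    i5 <- sample.int(n5, nDraw, replace = TRUE)
    i11 <- sample.int(n11, nDraw, replace = TRUE)
    list(i5 = i5, i11 = i11)
  })
  keep <- !duplicated(rng$i5 * (n11 + 1L) + rng$i11)
  i5 <- rng$i5[keep]; i11 <- rng$i11[keep]
  res5 <- m5[i5, paste0("p", P5N3_POSITIONS), drop = FALSE]
  res11 <- m11[i11, paste0("p", P11N4_POSITIONS), drop = FALSE]
  cand <- cbind(
    data.frame(p5_module = as.character(m5$module_id)[i5],
               p11_module = as.character(m11$module_id)[i11],
               stringsAsFactors = FALSE),
    res11, res5)
  rownames(cand) <- NULL
  ## residue-level id; distinct module pairs can yield the same residues,
  ## keep the first occurrence
  resCols <- paste0("p", KEY_POSITIONS)
  ids <- do.call(paste, c(lapply(KEY_POSITIONS, function(p)
    paste0(p, cand[[paste0("p", p)]])), list(sep = "/")))
  first <- !duplicated(ids)
  cand <- cand[first, , drop = FALSE]
  cand$variant_id <- ids[first]
  cand <- cand[c("variant_id", "p5_module", "p11_module", resCols)]
  rownames(cand) <- NULL
  new("CombinatorialPool", target = target, candidates = cand,
      positives = data.frame(variant_id = character(), activity = numeric(),
                             stringsAsFactors = FALSE),
      provenance = list(p5_modules = as.character(m5$module_id),
                        p11_modules = as.character(m11$module_id),
                        oversampling = oversampling, seed = seed))
}

## Evaluate an expression under a local RNG seed without disturbing the
## caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Attach sequenced positives to a pool
#'
#' @param pool a CombinatorialPool.
#' @param positives data.frame (`variant_id`, `activity`) of sequenced
#'   positives; must be a subset of the pool's candidates.
#' @return the pool with positives set.
#' @export
setPoolPositives <- function(pool, positives) {
  stopifnot(is(pool, "CombinatorialPool"))
  if (!all(c("variant_id", "activity") %in% names(positives)))
    stop("positives need columns variant_id, activity", call. = FALSE)
  missing <- setdiff(positives$variant_id, pool@candidates$variant_id)
  if (length(missing))
    stop("positive variants not among candidates: ",
         paste(head(missing, 3L), collapse = ", "), call. = FALSE)
  pool@positives <- positives
  validObject(pool)
  pool
}

#' Label a pool under positive-only sequencing
#'
#' Every candidate yields one screening record. Sequenced positives keep
#' their measured activity score and `measured = TRUE`; all other candidates
#' are assumed negative (activity 0, label 0, `measured = FALSE`) because
#' unsequenced combinations were not observed among positives.
#'
#' @param pool a CombinatorialPool with positives set.
#' @return data.frame of screening records (one per candidate).
#' @export
labelPool <- function(pool) {
  stopifnot(is(pool, "CombinatorialPool"))
  cand <- pool@candidates
  pos <- pool@positives
  missing <- setdiff(pos$variant_id, cand$variant_id)
  if (length(missing))
    stop("positives not among candidates: ",
         paste(head(missing, 3L), collapse = ", "), call. = FALSE)
  idx <- match(cand$variant_id, pos$variant_id)
  rec <- cand
  rec$target <- pool@target
  rec$activity <- ifelse(is.na(idx), 0, pos$activity[idx])
  rec$label <- as.integer(!is.na(idx))
  rec$measured <- !is.na(idx)
  regs <- extractRegions(pool@target)
  rec$r5N3 <- regs$r5N3
  rec$r11N4 <- regs$r11N4
  rownames(rec) <- NULL
  rec
}

#' Join measured module activities onto pool records
#'
#' Adds the Mact feature columns: the measured cleavage activity of each
#' record's p5N3 module on the target's 5N3 region and of its p11N4 module on
#' the 11N4 region. A module absent from the library yields NA (an explicit
#' missing-value code, never a silent zero).
#'
#' @param records data.frame from [labelPool()].
#' @param p5Lib,p11Lib ModuleLibrary objects.
#' @return records with `act5` and `act11` columns added.
#' @export
joinModuleActivities <- function(records, p5Lib, p11Lib) {
  stopifnot(is(p5Lib, "ModuleLibrary"), is(p11Lib, "ModuleLibrary"))
  a5 <- moduleActivities(p5Lib)
  a11 <- moduleActivities(p11Lib)
  i5 <- match(records$p5_module, rownames(a5))
  i11 <- match(records$p11_module, rownames(a11))
  j5 <- match(records$r5N3, colnames(a5))
  j11 <- match(records$r11N4, colnames(a11))
  records$act5 <- ifelse(is.na(i5) | is.na(j5), NA_real_,
                         a5[cbind(i5, j5)])
  records$act11 <- ifelse(is.na(i11) | is.na(j11), NA_real_,
                          a11[cbind(i11, j11)])
  records
}
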