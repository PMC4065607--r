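## Generative simulator for the combinatorial screen.
##
## The ground-truth activity of a full variant on a target is an additive
## latent-scale model squashed into [0,1]:
##
##   score = clip01( b0 + w5 * C5(m5, r5N3) + w11 * C11(m11, r11N4)
##                   + nonspecific(variant) + M2M(variant)
##                   + M2T(variant, target) + noise )
##
## where C5/C11 are latent module compatibilities (amplitude times an
## exponential decay in Hamming distance between the module's preferred
## region target and the actual one), nonspecific effects are per
## residue-at-position terms, M2M terms penalize or reward simultaneous
## residue pairs, and M2T terms encode residue-nucleotide preferences at
## contacting position pairs. Labels threshold the score at tau_active;
## scores >= 0.8 are "strong". The planted named effects mirror the
## screening observations the model family is meant to capture: a
## deleterious 44F, a deleterious 32K, and a deleterious 44R+77R pair.
## The generative form is this package's own construction: it is the minimal
## structure making every modeled feature class (module activities, main
## sequence effects, M2M and M2T interactions) identifiable.

## ---- module libraries -------------------------------------------------

#' Simulate the p5N3 and p11N4 module libraries
#'
#' Each module half gets random residues at its side's key positions, a
#' preferred region target (all region targets covered) and an amplitude;
#' its latent compatibility with a region target decays exponentially with
#' Hamming distance from the preference. Measured activities add Gaussian
#' noise and are clipped to [0,1]. Every region target is covered by at
#' least one active module by construction (the dedicated module's amplitude
#' exceeds the activity threshold).
#'
#' @param seed integer seed.
#' @param sizes named integer vector: number of modules per side.
#' @param params list: `decay` (per-mismatch attenuation), `ampRange`
#'   (amplitude range), `measNoise` (sd of measurement noise).
#' @return list with ModuleLibrary elements `p5` and `p11`.
#' @export
simulateModuleLibraries <- function(seed = 1L,
                                    sizes = c(p5N3 = 640L, p11N4 = 512L),
                                    params = list()) {
  p <- modifyList(list(decay = 0.3, ampRange = c(0.5, 1), measNoise = 0.04),
                  params)
  if (any(sizes < 1L)) stop(validationError("library sizes must be >= 1"))
  mk <- function(region, n, sd) {
    space <- enumerateRegionSpace(sub("^p", "", region))
    pos <- if (region == "p5N3") P5N3_POSITIONS else P11N4_POSITIONS
    withSeed(sd, {
      k <- min(n, length(space))
      prefs <- character(n)
      prefs[seq_len(k)] <- space[seq_len(k)]
      if (n > k)
        prefs[(k + 1L):n] <- sample(space, n - k, replace = TRUE)
      amp <- runif(n, p$ampRange[1L], p$ampRange[2L])
      res <- lapply(pos, function(pp)
        sample(DEFAULT_ALPHABETS[[as.character(pp)]], n, replace = TRUE))
      names(res) <- paste0("p", pos)
      modules <- data.frame(module_id = sprintf("%s-%03d", region, seq_len(n)),
                            res, stringsAsFactors = FALSE)
      D <- vapply(space, function(s) hammingTo(s, prefs), numeric(n))
      latent <- amp * p$decay^D
      dimnames(latent) <- list(modules$module_id, space)
      measured <- clip01(latent + rnorm(length(latent), 0, p$measNoise))
      dimnames(measured) <- dimnames(latent)
      new("ModuleLibrary", region = region, modules = modules,
          activities = measured, latent = latent)
    })
  }
  list(p5 = mk("p5N3", sizes[["p5N3"]], childSeed(seed, 11L)),
       p11 = mk("p11N4", sizes[["p11N4"]], childSeed(seed, 12L)))
}

## ---- ground-truth model ----------------------------------------------

## Planted named effects, on the latent activity scale.
plantedNonspecific <- function() {
  data.frame(position = c(44L, 32L), residue = c("F", "K"),
             effect = c(-0.4, -0.3), stringsAsFactors = FALSE)
}
plantedM2M <- function() {
  data.frame(
    pos1 = c(44L, 68L, 33L, 44L, 70L, 32L, 68L, 30L, 70L, 30L, 44L, 38L),
    res1 = c("R", "N", "R", "K", "S", "T", "Y", "K", "N", "H", "N", "Y"),
    pos2 = c(77L, 70L, 40L, 33L, 38L, 77L, 75L, 40L, 75L, 33L, 68L, 77L),
    res2 = c("R", "K", "R", "H", "A", "V", "E", "Q", "R", "G", "S", "K"),
    effect = c(-0.7, -0.5, -0.5, 0.4, -0.4, 0.35, -0.4, -0.4, -0.45, -0.4,
               0.35, -0.45),
    stringsAsFactors = FALSE)
}
## Residue-nucleotide preferences at contacting position pairs: residue 70
## contacts 5N3 bases 1-2, residue 44 base 2, residue 68 base 3; residue 33
## contacts 11N4 base 3, residues 30/38 base 2, residue 40 base 4.
plantedM2T <- function() {
  data.frame(
    position = c(70L, 70L, 44L, 44L, 68L, 68L, 33L, 33L, 38L, 30L, 70L, 40L),
    residue = c("R", "S", "K", "Q", "Y", "R", "Y", "H", "Q", "N", "K", "K"),
    region = c(rep("r5N3", 6L), rep("r11N4", 4L), "r5N3", "r11N4"),
    index = c(1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 2L, 2L, 1L, 4L),
    nt = c("G", "A", "T", "A", "C", "G", "G", "T", "A", "G", "T", "C"),
    effect = c(0.45, 0.38, 0.38, 0.3, 0.38, 0.3, 0.38, 0.3, 0.38, 0.3,
               -0.38, -0.3),
    stringsAsFactors = FALSE)
}

#' Build the generative ground-truth model
#'
#' Simulates the two module libraries and draws the effect tables: random
#' small non-specific effects per residue-at-position (with the planted
#' 44F and 32K penalties), the planted deleterious 44R+77R pair plus a few
#' random M2M pairs, and the planted residue-nucleotide (M2T) preferences at
#' contacting positions.
#'
#' @param seed integer seed.
#' @param librarySizes passed to [simulateModuleLibraries()].
#' @param params overrides for the latent-model parameters: `b0` (baseline),
#'   `w5`, `w11` (module-compatibility weights), `sigma` (latent noise sd),
#'   `tau_active` (activity threshold, default 0.25), `strong` (0.8),
#'   `sd_nonspecific` (sd of random non-specific effects), `p_zero`
#'   (probability a residue effect is exactly 0).
#' @param zeroSequenceEffects if TRUE, all sequence-level effects
#'   (non-specific, M2M, M2T) are zeroed: a module-compatibility-only world
#'   in which module activities alone determine labels.
#' @return A [GroundTruthModel-class].
#' @export
groundTruthModel <- function(seed = 1L,
                             librarySizes = c(p5N3 = 640L, p11N4 = 512L),
                             params = list(),
                             zeroSequenceEffects = FALSE) {
  ## The latent baseline b0 is calibrated so the default world reproduces the
  ## campaign's ~15 positives per ~1160-variant pool; the zeroed-effects
  ## world (no sequence-level terms) needs a shallower baseline for the same
  ## positive rate, since the positive tail otherwise comes from favorable
  ## sequence effects.
  p <- modifyList(list(b0 = if (zeroSequenceEffects) -0.53 else -1.05,
                       w5 = 0.5, w11 = 0.5, sigma = 0.15,
                       tau_active = 0.25, strong = 0.8,
                       sd_nonspecific = 0.06, p_zero = 0.4,
                       libDecay = 0.3, ampRange = c(0.5, 1),
                       measNoise = 0.08),
                  params)
  libs <- simulateModuleLibraries(
    childSeed(seed, 21L), librarySizes,
    params = list(decay = p$libDecay, ampRange = p$ampRange,
                  measNoise = p$measNoise))
  if (zeroSequenceEffects) {
    ns <- data.frame(position = integer(), residue = character(),
                     effect = numeric(), stringsAsFactors = FALSE)
    m2m <- data.frame(pos1 = integer(), res1 = character(), pos2 = integer(),
                      res2 = character(), effect = numeric(),
                      stringsAsFactors = FALSE)
    m2t <- plantedM2T()[0L, ]
  } else {
    ns <- withSeed(childSeed(seed, 22L), {
      tab <- do.call(rbind, lapply(names(DEFAULT_ALPHABETS), function(pp) {
        res <- DEFAULT_ALPHABETS[[pp]]
        data.frame(position = as.integer(pp), residue = res,
                   effect = ifelse(res == WT_RESIDUES[[pp]], 0,
                                   rnorm(length(res), 0, p$sd_nonspecific) *
                                     rbinom(length(res), 1L, 1 - p$p_zero)),
                   stringsAsFactors = FALSE)
      }))
      tab
    })
    planted <- plantedNonspecific()
    for (i in seq_len(nrow(planted))) {
      j <- ns$position == planted$position[i] & ns$residue == planted$residue[i]
      ns$effect[j] <- planted$effect[i]
    }
    m2m <- plantedM2M()
    m2t <- plantedM2T()
    ## planted pair effects are pure epistasis: their component residues are
    ## individually neutral, so the pair's effect is attributable to the
    ## interaction term alone
    comp <- rbind(data.frame(position = m2m$pos1, residue = m2m$res1),
                  data.frame(position = m2m$pos2, residue = m2m$res2))
    for (i in seq_len(nrow(comp))) {
      j <- ns$position == comp$position[i] & ns$residue == comp$residue[i]
      ns$effect[j] <- 0
    }
  }
  new("GroundTruthModel", p5 = libs$p5, p11 = libs$p11,
      params = p, nonspecific = ns, m2m = m2m, m2t = m2t,
      seed = as.integer(seed))
}

setMethod("show", "GroundTruthModel", function(object) {
  cat("GroundTruthModel (seed ", object@seed, ")\n",
      "  libraries: ", nrow(object@p5@modules), " p5N3 / ",
      nrow(object@p11@modules), " p11N4 modules\n",
      "  effects: ", nrow(object@nonspecific), " non-specific, ",
      nrow(object@m2m), " M2M, ", nrow(object@m2t), " M2T\n",
      "  tau_active ", object@params$tau_active, ", strong ",
      object@params$strong, "\n", sep = "")
})

## Sum of sequence-level effects for a candidate table on one target.
sequenceEffects <- function(model, cand, r5, r11) {
  n <- nrow(cand)
  tot <- numeric(n)
  ns <- model@nonspecific
  if (nrow(ns)) {
    key <- paste0(ns$position, ns$residue)
    eff <- setNames(ns$effect, key)
    for (pos in KEY_POSITIONS) {
      v <- eff[paste0(pos, cand[[paste0("p", pos)]])]
      v[is.na(v)] <- 0
      tot <- tot + v
    }
  }
  m2m <- model@m2m
  for (i in seq_len(nrow(m2m)))
    tot <- tot + m2m$effect[i] *
      (cand[[paste0("p", m2m$pos1[i])]] == m2m$res1[i] &
         cand[[paste0("p", m2m$pos2[i])]] == m2m$res2[i])
  m2t <- model@m2t
  for (i in seq_len(nrow(m2t))) {
    reg <- if (m2t$region[i] == "r5N3") r5 else r11
    nt <- substr(reg, m2t$index[i], m2t$index[i])
    tot <- tot + m2t$effect[i] *
      (cand[[paste0("p", m2t$position[i])]] == m2t$residue[i] &
         nt == m2t$nt[i])
  }
  tot
}

#' Ground-truth activity of candidate variants on a target
#'
#' Evaluates the latent additive model for each candidate (requires module
#' provenance columns `p5_module`, `p11_module` for the compatibility
#' lookup), adds Gaussian noise with sd `sigma` (set `sigma = 0` in
#' `model@params` for a noise-free oracle; repeated calls with the same
#' `noiseSeed` are identical), clips to [0,1] and thresholds.
#'
#' @param model a [GroundTruthModel-class].
#' @param candidates candidate data.frame (residues + module columns), e.g.
#'   [poolCandidates()].
#' @param target 22-base target string.
#' @param noiseSeed seed for the noise draw.
#' @return data.frame (`variant_id`, `score`, `label`, `strong`).
#' @export
groundTruthActivity <- function(model, candidates, target, noiseSeed = 1L) {
  stopifnot(is(model, "GroundTruthModel"))
  target <- assertDna(target, 22L)
  regs <- extractRegions(target)
  p <- model@params
  lat5 <- moduleActivities(model@p5, latent = TRUE)
  lat11 <- moduleActivities(model@p11, latent = TRUE)
  c5 <- lat5[cbind(match(candidates$p5_module, rownames(lat5)),
                   match(regs$r5N3, colnames(lat5)))]
  c11 <- lat11[cbind(match(candidates$p11_module, rownames(lat11)),
                     match(regs$r11N4, colnames(lat11)))]
  if (anyNA(c5) || anyNA(c11))
    stop(validationError("candidate modules missing from model libraries"))
  eff <- sequenceEffects(model, candidates, regs$r5N3, regs$r11N4)
  noise <- if (p$sigma > 0)
    withSeed(noiseSeed, rnorm(nrow(candidates), 0, p$sigma)) else 0
  score <- clip01(p$b0 + p$w5 * c5 + p$w11 * c11 + eff + noise)
  data.frame(variant_id = candidates$variant_id, score = score,
             label = as.integer(score >= p$tau_active),
             strong = score >= p$strong, stringsAsFactors = FALSE)
}

## ---- screening dataset -------------------------------------------------

## top-n module subset for a region target (deterministic tie-break on id)
topModules <- function(lib, regionTarget, n) {
  act <- moduleActivities(lib)[, regionTarget]
  ids <- rownames(moduleActivities(lib))
  ord <- order(-act, ids)
  take <- head(ord, n)
  moduleResidues(lib)[take, , drop = FALSE]
}

#' Generate a full synthetic combinatorial screening dataset
#'
#' Emulates the screening campaign: for each target (distinct random
#' GTAC-centered pseudopalindromes), the best modules per side are selected
#' from the libraries, a candidate pool is assembled by oversampled random
#' module pairing, ground-truth activities are evaluated, and positive-only
#' sequencing is applied (positives keep their scores; unsequenced
#' candidates become assumed negatives). Targets whose pool has no positive
#' are re-assembled with a fresh seed up to `maxRetries` times, so every
#' target ends with at least one positive mutant.
#'
#' @param model a [GroundTruthModel-class].
#' @param nTargets number of screening targets (default 251, the campaign
#'   scale).
#' @param modulesPerPool modules selected per side for each pool (default 35,
#'   giving a theoretical diversity of 1225 and, at triple oversampling,
#'   an expected distinct pool size of about 1160).
#' @param oversampling assembly oversampling factor (default 3).
#' @param seed master seed.
#' @param maxRetries re-assembly budget per target.
#' @return A [ScreeningSet-class].
#' @export
generateScreeningDataset <- function(model, nTargets = 251L,
                                     modulesPerPool = 35L, oversampling = 3,
                                     seed = 1L, maxRetries = 20L) {
  stopifnot(is(model, "GroundTruthModel"))
  space5 <- enumerateRegionSpace("5N3")
  space11 <- enumerateRegionSpace("11N4")
  maxT <- length(space5) * length(space11)
  if (nTargets > maxT)
    stop(validationError("more targets requested than distinct half-sites"))
  ## Candidate targets are drawn in a shuffled order; a target whose pools
  ## yield no positive (after a few re-assemblies) is rejected and replaced,
  ## mirroring the campaign property that every kept target had at least one
  ## positive mutant.
  budget <- min(maxT, nTargets + maxRetries * max(10L, nTargets %/% 4L))
  combos <- withSeed(childSeed(seed, 1L), sample.int(maxT, budget))
  recs <- vector("list", nTargets)
  targets <- character(nTargets)
  retries <- integer(nTargets)
  skipped <- 0L
  i <- 0L
  for (ci in seq_along(combos)) {
    if (i >= nTargets) break
    r5i <- space5[(combos[ci] - 1L) %% 64L + 1L]
    r11i <- space11[(combos[ci] - 1L) %/% 64L + 1L]
    tgt <- targetFromRegions(r5i, r11i)
    m5 <- topModules(model@p5, r5i, modulesPerPool)
    m11 <- topModules(model@p11, r11i, modulesPerPool)
    pos <- NULL
    for (attempt in 0:2) {
      pool <- assemblePool(tgt, m5, m11, oversampling,
                           seed = childSeed(seed, 100L + ci + 100000L * attempt))
      gt <- groundTruthActivity(model, poolCandidates(pool), tgt,
                                noiseSeed = childSeed(seed, 500000L + ci +
                                                        100000L * attempt))
      pos <- gt[gt$label == 1L, c("variant_id", "score")]
      if (nrow(pos)) break
    }
    if (!nrow(pos)) { skipped <- skipped + 1L; next }
    i <- i + 1L
    targets[i] <- tgt
    retries[i] <- attempt
    names(pos)[2L] <- "activity"
    pool <- setPoolPositives(pool, pos)
    recs[[i]] <- labelPool(pool)
  }
  if (i < nTargets)
    stop("calibration failure: could not find ", nTargets,
         " targets with at least one positive within the retry budget",
         call. = FALSE)
  records <- do.call(rbind, recs)
  records <- joinModuleActivities(records, model@p5, model@p11)
  records <- records[SCREENING_COLUMNS]
  rownames(records) <- NULL
  new("ScreeningSet", records = records, targets = targets,
      meta = list(seed = seed, nTargets = nTargets,
                  modulesPerPool = modulesPerPool,
                  oversampling = oversampling, retries = retries,
                  rejected_targets = skipped, params = model@params))
}

## ---- specificity dataset ------------------------------------------------

#' Generate the mutant x 5N3-target specificity matrix
#'
#' Simulates p5N3-mutated proteins assayed on all 64 5N3 targets. Each mutant
#' has a preferred target, a breadth parameter (per-mismatch attenuation) and
#' an amplitude positively tied to breadth, so highly active mutants tend to
#' be less specific (the activity/specificity tension the trade-off ranking
#' addresses). Every mutant is active on at least one target; the default
#' calibration puts the positive fraction near the 6.6% screening-scale rate.
#' A wild-type reference row (`WT`, preferring the wild-type 5N3 target) is
#' included for specificity thresholds.
#'
#' @param nMutants number of mutants (default 2576).
#' @param seed integer seed.
#' @param tau activity threshold for positives (default 0.25).
#' @param params overrides: `decayRange`, `ampFloor`, `ampScale`, `ampNoise`,
#'   `noise` (assay noise sd).
#' @param ensureActive if TRUE (default), emulate the assayed validation set:
#'   every mutant is active on at least one target (amplitudes floored above
#'   `tau`, rows rescued at their preferred target). With FALSE the function
#'   emulates an open candidate space, where the narrowest (most specific)
#'   mutants can be inactive everywhere — the regime in which ranking
#'   candidates purely by specificity returns dead proteins.
#' @return list: `activities` (matrix mutants x 64 targets), `mutants`
#'   (data.frame with residues, preference, breadth, amplitude), `tau`,
#'   `wt_id`.
#' @export
generateSpecificityDataset <- function(nMutants = 2576L, seed = 1L,
                                       tau = 0.25, params = list(),
                                       ensureActive = TRUE) {
  p <- modifyList(list(decayRange = c(0.15, 0.42), ampMax = 0.82,
                       ampMid = 0.225, ampWidth = 0.012, ampNoise = 0.05,
                       noise = 0.02),
                  params)
  space <- enumerateRegionSpace("5N3")
  wt5 <- extractRegions(wtTarget())$r5N3
  withSeed(childSeed(seed, 31L), {
    decay <- runif(nMutants, p$decayRange[1L], p$decayRange[2L])
    ## steep logistic amplitude-breadth frontier: ultra-narrow binders are
    ## weak, activity rises sharply once breadth passes ampMid and then
    ## saturates, so mutants just past the rise combine useful activity with
    ## near-specialist specificity (the compromise the trade-off score finds)
    amp <- clip01(p$ampMax * stats::plogis((decay - p$ampMid) / p$ampWidth) +
                    rnorm(nMutants, 0, p$ampNoise))
    if (ensureActive) amp <- pmax(amp, tau + 0.05)
    pref <- sample(space, nMutants, replace = TRUE)
    res <- lapply(P5N3_POSITIONS, function(pp)
      sample(DEFAULT_ALPHABETS[[as.character(pp)]], nMutants, replace = TRUE))
    names(res) <- paste0("p", P5N3_POSITIONS)
    ids <- sprintf("mut-%04d", seq_len(nMutants))
    ## wild-type reference row
    ids <- c("WT", ids)
    pref <- c(wt5, pref)
    decay <- c(0.25, decay)
    amp <- c(0.6, amp)
    res <- lapply(seq_along(res), function(k)
      c(WT_RESIDUES[[as.character(P5N3_POSITIONS[k])]], res[[k]]))
    names(res) <- paste0("p", P5N3_POSITIONS)
    D <- vapply(space, function(s) hammingTo(s, pref), numeric(length(pref)))
    A <- amp * decay^D + matrix(rnorm(length(pref) * 64L, 0, p$noise),
                                ncol = 64L)
    A <- clip01(A)
    dimnames(A) <- list(ids, space)
    ## validation set only: every mutant active somewhere (lift the
    ## preferred-target activity of rows the noise pushed below threshold)
    if (ensureActive) {
      none <- rowSums(A >= tau) == 0L
      if (any(none))
        A[cbind(which(none), match(pref[none], space))] <- tau + 0.02
    }
    mutants <- data.frame(mutant_id = ids, pref = pref, breadth = decay,
                          amplitude = amp, res, stringsAsFactors = FALSE)
    list(activities = A, mutants = mutants, tau = tau, wt_id = "WT")
  })
}

#' Simulate model-predicted activity profiles for a specificity dataset
#'
#' Emulates the error structure of sequence-based activity predictions on a
#' mutant x target activity matrix: a model infers each mutant's binding
#' preference pattern well but resolves its overall amplitude poorly (the
#' screening labels are binary, and expression/stability determinants of
#' amplitude are hidden). Predicted profiles therefore multiply the true
#' breadth pattern by an amplitude estimate with substantial error, plus
#' small per-pair noise. In consequence, ranking candidates purely by
#' predicted specificity surfaces narrow binders regardless of whether they
#' are truly active — the failure mode the activity/specificity trade-off
#' score corrects.
#'
#' @param sp a dataset from [generateSpecificityDataset()].
#' @param ampError sd of the amplitude estimation error (default 0.25).
#' @param noise sd of per-pair prediction noise (default 0.03).
#' @param seed integer seed.
#' @return matrix of predicted activities, same shape as `sp$activities`.
#' @export
simulatePredictedActivities <- function(sp, ampError = 0.35, noise = 0.02,
                                        seed = 1L) {
  mut <- sp$mutants
  space <- colnames(sp$activities)
  withSeed(childSeed(seed, 41L), {
    ampHat <- clip01(mut$amplitude + rnorm(nrow(mut), 0, ampError))
    D <- vapply(space, function(s) hammingTo(s, mut$pref),
                numeric(nrow(mut)))
    P <- ampHat * mut$breadth^D +
      matrix(rnorm(nrow(mut) * length(space), 0, noise), ncol = length(space))
    P <- clip01(P)
    dimnames(P) <- dimnames(sp$activities)
    P
  })
}

#' Dump the ground truth to JSON
#'
#' Writes the effect tables, parameters and module residues so downstream
#' analyses and tests can compute counterfactual oracles without the model
#' object.
#'
#' @param model a [GroundTruthModel-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(model, path) {
  obj <- list(seed = model@seed, params = model@params,
              nonspecific = model@nonspecific, m2m = model@m2m,
              m2t = model@m2t,
              p5_modules = moduleResidues(model@p5),
              p11_modules = moduleResidues(model@p11))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
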