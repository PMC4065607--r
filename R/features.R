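## Design-matrix encodings.
##
## Three representations of a screening record (variant, target):
##  * categorical — one factor column per protein key position and per target
##    position in the 5N3/11N4 regions, plus two real module-activity columns;
##  * Bin1 — one-hot expansion of every categorical column;
##  * Bin2 — Bin1 plus elementwise products of pairs of order-1 binary
##    columns (second-order interactions), annotated M2M/M2T and intra/cross.
## The central 2N4 region contributes no features: its effect on cleavage is
## independent of the other regions and all modeled targets are GTAC-centered.

## position keys of the sequence features
proteinKeys <- function() paste0("P", KEY_POSITIONS)
targetKeys <- function() c(paste0("T5N3.", 1:3), paste0("T11N4.", 1:4))

keySide <- function(key) {
  pos <- suppressWarnings(as.integer(sub("^P", "", key)))
  ifelse(grepl("^T5N3", key) | (!is.na(pos) & pos %in% P5N3_POSITIONS),
         "p5N3",
         ifelse(grepl("^T11N4", key) |
                  (!is.na(pos) & pos %in% P11N4_POSITIONS),
                "p11N4", "none"))
}

keySource <- function(key) ifelse(grepl("^P", key), "protein_seq", "target_seq")

## Fetch the character value vector of one position key from records
keyValues <- function(records, key) {
  if (grepl("^P", key)) {
    col <- paste0("p", sub("^P", "", key))
    if (is.null(records[[col]]))
      stop(validationError(paste("records lack residue column", col)))
    return(as.character(records[[col]]))
  }
  k <- as.integer(sub(".*\\.", "", key))
  reg <- if (grepl("^T5N3", key)) "r5N3" else "r11N4"
  if (is.null(records[[reg]]))
    stop(validationError(paste("records lack region column", reg)))
  substr(as.character(records[[reg]]), k, k)
}

recordsFrom <- function(x) {
  if (is(x, "ScreeningSet")) screeningRecords(x)
  else if (is.data.frame(x)) x
  else stop(validationError("expected a ScreeningSet or records data.frame"))
}

emptyColumnData <- function(n = 0L) {
  data.frame(name = character(n), source = character(n),
             position = character(n), level = character(n),
             module_side = character(n), order = integer(n),
             parent1 = rep(NA_character_, n), parent2 = rep(NA_character_, n),
             iclass = rep("none", n), stringsAsFactors = FALSE)
}

#' Encode screening records as the categorical dataset
#'
#' One factor column per protein key position (10 by default) and per target
#' position in the 5N3 and 11N4 regions (7), plus two real-valued columns:
#' the cleavage activity of the record's p5N3 module on the target's 5N3
#' region (`MACT5`) and of its p11N4 module on the 11N4 region (`MACT11`).
#' Missing module activities stay `NA` — an explicit missing-value code,
#' never a silent zero. No 2N4-derived column exists.
#'
#' @param x a [ScreeningSet-class] or records data.frame with residue columns
#'   `p30`..`p77`, region columns `r5N3`, `r11N4`, and activities `act5`,
#'   `act11`.
#' @return A [FeatureMatrix-class] with `encoding = "categorical"`.
#' @export
encodeCategorical <- function(x) {
  rec <- recordsFrom(x)
  keys <- c(proteinKeys(), targetKeys())
  df <- as.data.frame(lapply(keys, function(k) factor(keyValues(rec, k))),
                      col.names = keys, stringsAsFactors = TRUE)
  if (is.null(rec$act5) || is.null(rec$act11))
    stop(validationError("records lack module-activity columns act5/act11"))
  df$MACT5 <- as.numeric(rec$act5)
  df$MACT11 <- as.numeric(rec$act11)
  cd <- emptyColumnData(length(keys) + 2L)
  cd$name <- c(keys, "MACT5", "MACT11")
  cd$position <- c(keys, "MACT5", "MACT11")
  cd$source <- c(keySource(keys), "module_activity", "module_activity")
  cd$module_side <- c(keySide(keys), "p5N3", "p11N4")
  cd$order <- 1L
  cd$level <- NA_character_
  new("FeatureMatrix", x = df, columnData = cd, encoding = "categorical",
      rowTarget = as.character(rec$target))
}

#' One-hot (Bin1) encoding
#'
#' Expands every categorical column into one binary column per observed level
#' (`P44=R`, `T5N3.2=G`, ...); module-activity columns pass through as reals.
#' Exactly one indicator per position block is 1 in every row. At prediction
#' time, encoding against a template whose level set misses a record's level
#' yields an all-zero block for that position (documented contract for unseen
#' levels).
#'
#' @param x ScreeningSet or records data.frame.
#' @param levels optional named list of level sets per position key (training
#'   levels); defaults to the levels observed in `x`.
#' @return A [FeatureMatrix-class] with `encoding = "bin1"` and a sparse
#'   design matrix.
#' @export
encodeBin1 <- function(x, levels = NULL) {
  rec <- recordsFrom(x)
  keys <- c(proteinKeys(), targetKeys())
  n <- nrow(rec)
  blocks <- vector("list", length(keys))
  cds <- vector("list", length(keys))
  for (ki in seq_along(keys)) {
    k <- keys[ki]
    vals <- keyValues(rec, k)
    lv <- if (!is.null(levels)) levels[[k]] else sort(unique(vals))
    if (is.null(lv)) lv <- character()  # position absent from the template
    f <- match(vals, lv)
    ok <- which(!is.na(f))
    m <- Matrix::sparseMatrix(i = ok, j = f[ok], x = 1,
                              dims = c(n, length(lv)))
    colnames(m) <- if (length(lv)) paste0(k, "=", lv) else character()
    blocks[[ki]] <- m
    nl <- length(lv)
    cd <- emptyColumnData(nl)
    cd$name <- colnames(m)
    cd$position <- rep(k, nl)
    cd$level <- lv
    cd$source <- rep(keySource(k), nl)
    cd$module_side <- rep(keySide(k), nl)
    cd$order <- rep(1L, nl)
    cds[[ki]] <- cd
  }
  if (is.null(rec$act5) || is.null(rec$act11))
    stop(validationError("records lack module-activity columns act5/act11"))
  act <- cbind(MACT5 = as.numeric(rec$act5), MACT11 = as.numeric(rec$act11))
  if (anyNA(act)) {
    miss <- 1 * is.na(act)
    colnames(miss) <- c("MACT5.missing", "MACT11.missing")
    act[is.na(act)] <- 0
    act <- cbind(act, miss)
  }
  actM <- Matrix::Matrix(act, sparse = TRUE)
  cdA <- emptyColumnData(ncol(act))
  cdA$name <- colnames(act)
  cdA$position <- colnames(act)
  cdA$source <- "module_activity"
  cdA$module_side <- rep_len(c("p5N3", "p11N4"), ncol(act))
  cdA$order <- 1L
  cdA$level <- NA_character_
  X <- do.call(cbind, c(blocks, list(actM)))
  cd <- do.call(rbind, c(cds, list(cdA)))
  rownames(cd) <- NULL
  new("FeatureMatrix", x = X, columnData = cd, encoding = "bin1",
      rowTarget = as.character(rec$target))
}

## Per-position level index of each row (0 = level unseen) from a one-hot
## block; exploits that exactly one indicator per block is set.
positionLevelIndex <- function(X, cd) {
  keys <- unique(cd$position[cd$order == 1L &
                               cd$source %in% c("protein_seq", "target_seq")])
  out <- lapply(keys, function(k) {
    B <- which(cd$position == k & cd$order == 1L)
    as.integer(as.vector(X[, B, drop = FALSE] %*% seq_along(B)))
  })
  names(out) <- keys
  out
}

## Sparse indicator matrix for explicit (position1=level-index1,
## position2=level-index2) pairs. A product of two one-hot indicators is the
## indicator of the joint level, so each position pair costs one O(n) pass.
productMatrix <- function(levIdx, pos1, pos2, l1, l2, nlev2) {
  n <- length(levIdx[[1L]])
  cols <- vector("list", length(pos1))
  byPair <- split(seq_along(pos1), paste(pos1, pos2))
  trip_i <- vector("list", length(byPair))
  trip_j <- vector("list", length(byPair))
  ci <- 0L
  for (grp in byPair) {
    ci <- ci + 1L
    p1 <- pos1[grp[1L]]; p2 <- pos2[grp[1L]]
    m2 <- nlev2[grp[1L]]
    code <- levIdx[[p1]] * (m2 + 1L) + levIdx[[p2]]
    code[levIdx[[p1]] == 0L | levIdx[[p2]] == 0L] <- 0L
    want <- l1[grp] * (m2 + 1L) + l2[grp]
    hit <- match(code, want)
    ok <- which(!is.na(hit))
    trip_i[[ci]] <- ok
    trip_j[[ci]] <- grp[hit[ok]]
  }
  Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                       x = 1, dims = c(n, length(pos1)))
}

#' Append second-order interaction columns (Bin2)
#'
#' Elementwise products of unordered pairs of distinct order-1 binary
#' sequence columns. Pairs never combine two indicators of the same position
#' block (the product is identically zero) and module-activity columns do not
#' participate. The support filter ("more than `minSupport` non-zero
#' components") is applied per parent column by default (`filter =
#' "parent"`): both parents must have more than `minSupport` non-zero entries;
#' `filter = "product"` instead requires the product itself to pass. Products
#' of two protein columns are class M2M, protein x target products M2T;
#' target x target products (T2T) are off by default. A product's
#' `module_side` is the common side of its parents, or `"cross"` when the
#' parents span the p5N3 and p11N4 sides.
#'
#' @param bin1 a Bin1 [FeatureMatrix-class].
#' @param minSupport support threshold (default 200, the screening-scale
#'   value).
#' @param filter `"parent"` (default) or `"product"`.
#' @param includeT2T also build target x target products.
#' @return A [FeatureMatrix-class] with `encoding = "bin2"`.
#' @export
addInteractions <- function(bin1, minSupport = 200L,
                            filter = c("parent", "product"),
                            includeT2T = FALSE) {
  stopifnot(is(bin1, "FeatureMatrix"))
  if (bin1@encoding != "bin1")
    stop(validationError("addInteractions expects a Bin1 matrix"))
  if (minSupport < 0) stop("minSupport must be >= 0", call. = FALSE)
  filter <- match.arg(filter)
  X <- bin1@x
  cd <- bin1@columnData
  seqIdx <- which(cd$order == 1L &
                    cd$source %in% c("protein_seq", "target_seq"))
  supports <- Matrix::colSums(X[, seqIdx, drop = FALSE] != 0)
  elig <- if (filter == "parent") supports > minSupport
          else rep(TRUE, length(seqIdx))
  cand <- seqIdx[elig]
  if (length(cand) < 2L) {
    out <- bin1; out@encoding <- "bin2"; return(out)
  }
  pr <- t(combn(cand, 2L))
  samePos <- cd$position[pr[, 1L]] == cd$position[pr[, 2L]]
  pr <- pr[!samePos, , drop = FALSE]
  s1 <- cd$source[pr[, 1L]]; s2 <- cd$source[pr[, 2L]]
  iclass <- ifelse(s1 == "protein_seq" & s2 == "protein_seq", "M2M",
                   ifelse(s1 == "target_seq" & s2 == "target_seq",
                          "T2T", "M2T"))
  if (!includeT2T) {
    pr <- pr[iclass != "T2T", , drop = FALSE]
    iclass <- iclass[iclass != "T2T"]
  }
  if (!nrow(pr)) { out <- bin1; out@encoding <- "bin2"; return(out) }
  ## level index of each order-1 column within its position block
  lidx <- stats::ave(seq_along(cd$position), cd$position, FUN = seq_along)
  bsize <- table(cd$position[seqIdx])
  levIdx <- positionLevelIndex(X, cd)
  P <- productMatrix(levIdx, cd$position[pr[, 1L]], cd$position[pr[, 2L]],
                     lidx[pr[, 1L]], lidx[pr[, 2L]],
                     as.integer(bsize[cd$position[pr[, 2L]]]))
  psup <- Matrix::colSums(P)
  keep <- if (filter == "product") psup > minSupport else psup > 0
  pr <- pr[keep, , drop = FALSE]
  P <- P[, keep, drop = FALSE]
  iclass <- iclass[keep]
  if (!ncol(P)) { out <- bin1; out@encoding <- "bin2"; return(out) }
  n1 <- cd$name[pr[, 1L]]; n2 <- cd$name[pr[, 2L]]
  colnames(P) <- paste0(n1, "*", n2)
  side1 <- cd$module_side[pr[, 1L]]; side2 <- cd$module_side[pr[, 2L]]
  cd2 <- emptyColumnData(ncol(P))
  cd2$name <- colnames(P)
  cd2$source <- "interaction"
  cd2$position <- paste0(cd$position[pr[, 1L]], "*", cd$position[pr[, 2L]])
  cd2$level <- NA_character_
  cd2$module_side <- ifelse(side1 == side2, side1, "cross")
  cd2$order <- 2L
  cd2$parent1 <- n1
  cd2$parent2 <- n2
  cd2$iclass <- iclass
  new("FeatureMatrix", x = cbind(X, P),
      columnData = rbind(cd, cd2), encoding = "bin2",
      rowTarget = bin1@rowTarget)
}

#' Feature-group column masks
#'
#' Logical mask over a feature matrix's columns for each named group of the
#' ablation family. All SM-* groups extend the module-activity (Mact)
#' columns, mirroring the models being extensions of the module-activity
#' baseline.
#' @keywords internal
groupMask <- function(cd, group) {
  o1seq <- cd$order == 1L & cd$source %in% c("protein_seq", "target_seq")
  mact <- cd$source == "module_activity"
  ext <- cd$source == "external"
  o2 <- cd$order == 2L
  switch(group,
    "Mact" = mact,
    "SM-5" = mact | (o1seq & cd$module_side == "p5N3"),
    "SM-11" = mact | (o1seq & cd$module_side == "p11N4"),
    "SM-5_11" = mact | o1seq,
    "SM-M2M" = mact | o1seq | (o2 & cd$iclass == "M2M"),
    "SM-M2T" = mact | o1seq | (o2 & cd$iclass == "M2T"),
    "SM-Intra" = mact | o1seq | (o2 & cd$module_side %in% c("p5N3", "p11N4")),
    "SM-Cross" = mact | o1seq | (o2 & cd$module_side == "cross"),
    "SeqMact" = mact | o1seq | o2,
    "SeqMactFxStr" = mact | o1seq | o2 | ext,
    stop(validationError(paste("unknown feature group:", group)))
  )
}

#' Select a named feature-group subset
#'
#' Deterministic column subsets implementing the ablation-group algebra:
#' `Mact` (the two module-activity columns), `SM-5`/`SM-11` (Mact plus the
#' p5N3/p11N4 sequence features), `SM-5_11` (their union), `SM-M2M`/`SM-M2T`
#' (SM-5_11 plus protein-protein / protein-target interaction products),
#' `SM-Intra`/`SM-Cross` (SM-5_11 plus within-side / cross-side products) and
#' `SeqMact` (the union of all of them). `SeqMactFxStr` additionally admits
#' external real-valued columns (`source == "external"`, e.g. physics-based
#' scores supplied by the user) if present.
#'
#' @param fm a [FeatureMatrix-class].
#' @param group group name.
#' @return A [FeatureMatrix-class] restricted to the group's columns.
#' @export
selectGroup <- function(fm, group) {
  stopifnot(is(fm, "FeatureMatrix"))
  mask <- groupMask(fm@columnData, group)
  x <- if (is.data.frame(fm@x)) fm@x[, mask, drop = FALSE]
       else fm@x[, mask, drop = FALSE]
  cd <- fm@columnData[mask, , drop = FALSE]
  rownames(cd) <- NULL
  new("FeatureMatrix", x = x, columnData = cd, encoding = fm@encoding,
      rowTarget = fm@rowTarget)
}

#' Names of the supported feature groups
#' @return character vector of group names.
#' @export
featureGroups <- function() c("Mact", "SM-5", "SM-11", "SM-5_11", "SM-M2M",
                              "SM-M2T", "SM-Intra", "SM-Cross", "SeqMact",
                              "SeqMactFxStr")

#' Re-encode records against a template feature matrix
#'
#' Builds a design matrix with exactly the template's columns (training
#' levels and retained interaction pairs), so a scorer can encode unseen
#' records reproducibly. Levels absent from the template give all-zero
#' indicator blocks.
#'
#' @param x ScreeningSet or records data.frame.
#' @param template a Bin1/Bin2 [FeatureMatrix-class] from training.
#' @return A [FeatureMatrix-class] with the template's columns.
#' @export
encodeLike <- function(x, template) {
  stopifnot(is(template, "FeatureMatrix"))
  if (!template@encoding %in% c("bin1", "bin2"))
    stop(validationError("encodeLike needs a bin1/bin2 template"))
  rec <- recordsFrom(x)
  cd <- template@columnData
  o1 <- cd[cd$order == 1L, , drop = FALSE]
  lv <- split(o1$level[o1$source %in% c("protein_seq", "target_seq")],
              o1$position[o1$source %in% c("protein_seq", "target_seq")])
  b1 <- encodeBin1(rec, levels = lv)
  ## align order-1 columns to template order
  o1names <- cd$name[cd$order == 1L]
  i <- match(o1names, b1@columnData$name)
  if (anyNA(i))
    stop(validationError("template order-1 columns unavailable in records"))
  X1 <- b1@x[, i, drop = FALSE]
  o2 <- cd[cd$order == 2L, , drop = FALSE]
  if (nrow(o2)) {
    cdO1 <- cd[cd$order == 1L, , drop = FALSE]
    lidx <- stats::ave(seq_len(nrow(cdO1)), cdO1$position, FUN = seq_along)
    bsize <- table(cdO1$position)
    levIdx <- positionLevelIndex(X1, cdO1)
    j1 <- match(o2$parent1, cdO1$name)
    j2 <- match(o2$parent2, cdO1$name)
    P <- productMatrix(levIdx, cdO1$position[j1], cdO1$position[j2],
                       lidx[j1], lidx[j2],
                       as.integer(bsize[cdO1$position[j2]]))
    colnames(P) <- o2$name
    X <- cbind(X1, P)
  } else X <- X1
  new("FeatureMatrix", x = X, columnData = cd, encoding = template@encoding,
      rowTarget = as.character(rec$target))
}

#' Refilter interaction columns by support on a row subset
#'
#' Recomputes the support filter of [addInteractions()] on a subset of rows
#' (e.g. the training rows of a cross-validation replicate): order-1 columns
#' are always kept; an order-2 column is kept when both its parents (or the
#' product itself, under `filter = "product"`) have more than `minSupport`
#' non-zero entries among the rows.
#'
#' @param fm a Bin2 [FeatureMatrix-class].
#' @param rows integer or logical row index.
#' @param minSupport support threshold.
#' @param filter `"parent"` or `"product"`.
#' @return the filtered FeatureMatrix (all rows retained).
#' @export
supportFilter <- function(fm, rows, minSupport = 200L,
                          filter = c("parent", "product")) {
  stopifnot(is(fm, "FeatureMatrix"))
  filter <- match.arg(filter)
  cd <- fm@columnData
  sup <- Matrix::colSums(fm@x[rows, , drop = FALSE] != 0)
  keep <- rep(TRUE, nrow(cd))
  o2 <- which(cd$order == 2L)
  if (length(o2)) {
    if (filter == "parent") {
      ps <- sup[match(cd$parent1[o2], cd$name)] > minSupport &
        sup[match(cd$parent2[o2], cd$name)] > minSupport
      keep[o2] <- ps
    } else keep[o2] <- sup[o2] > minSupport
  }
  x <- fm@x[, keep, drop = FALSE]
  cdk <- cd[keep, , drop = FALSE]
  rownames(cdk) <- NULL
  new("FeatureMatrix", x = x, columnData = cdk, encoding = fm@encoding,
      rowTarget = fm@rowTarget)
}
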