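# Encodings and the feature-group algebra.

test_that("categorical encoding has one column per position plus activities", {
  fm <- encodeCategorical(fixRecords())
  cd <- featureColumns(fm)
  x <- featureValues(fm)
  expect_identical(ncol(x), 19L)  # 10 protein + 7 target + 2 activities
  expect_identical(sum(cd$source == "protein_seq"), 10L)
  expect_identical(sum(cd$source == "target_seq"), 7L)
  expect_identical(sum(cd$source == "module_activity"), 2L)
  # no 2N4-derived feature exists
  expect_false(any(grepl("2N4", cd$name)))
  # identical (variant, target) rows encode identically
  rec2 <- rbind(fixRecords()[1, ], fixRecords()[1, ])
  fm2 <- encodeCategorical(rec2)
  rows <- featureValues(fm2)
  expect_identical(unname(unlist(rows[1, ])), unname(unlist(rows[2, ])))
})

test_that("one-hot blocks are exhaustive and reconstruct the categorical", {
  rec <- fixRecords()
  b1 <- fixBin1()
  X <- featureValues(b1)
  cd <- featureColumns(b1)
  for (k in c("P44", "T5N3.2", "T11N4.4")) {
    block <- which(cd$position == k)
    expect_true(all(Matrix::rowSums(X[, block, drop = FALSE]) == 1))
    # argmax round-trip to the raw value
    lv <- cd$level[block]
    got <- lv[apply(as.matrix(X[1:50, block]), 1, which.max)]
    want <- if (k == "P44") rec$p44[1:50]
            else if (k == "T5N3.2") substr(rec$r5N3[1:50], 2, 2)
            else substr(rec$r11N4[1:50], 4, 4)
    expect_identical(got, want)
  }
  # unseen level at prediction time: all-zero block
  tmpl <- encodeBin1(rec[rec$p44 != "F", ])
  out <- encodeLike(rec[rec$p44 == "F", ][1:3, ], tmpl)
  blk <- which(featureColumns(out)$position == "P44")
  expect_true(all(featureValues(out)[, blk] == 0))
})

test_that("interaction products obey the support filter and pair rules", {
  # controlled supports: P44=A has 250 carriers, P44=B 150
  rec <- makeRecords(p44 = rep(c("A", "B"), c(250, 150)),
                     p77 = rep(c("V", "K"), 200))
  b1 <- encodeBin1(rec)
  b2 <- addInteractions(b1, minSupport = 200)
  cd2 <- featureColumns(b2)
  o2 <- cd2[cd2$order == 2L, ]
  # parent rule: pairs with the low-support parent are excluded
  expect_true(any(grepl("^P44=A\\*", o2$name)))
  expect_false(any(grepl("P44=B", o2$name)))
  # no product of two indicators of the same position
  p1pos <- sub("=[A-Z]*$", "", o2$parent1)
  p2pos <- sub("=[A-Z]*$", "", o2$parent2)
  expect_true(all(p1pos != p2pos))
  # product support never exceeds either parent's support
  X <- featureValues(b2)
  sup <- Matrix::colSums(X != 0)
  i1 <- match(o2$parent1, cd2$name); i2 <- match(o2$parent2, cd2$name)
  io <- match(o2$name, cd2$name)
  expect_true(all(sup[io] <= pmin(sup[i1], sup[i2])))
  # product-level filter keeps only products above the threshold
  b2p <- addInteractions(b1, minSupport = 120, filter = "product")
  cdp <- featureColumns(b2p)
  supP <- Matrix::colSums(featureValues(b2p) != 0)
  expect_true(all(supP[cdp$order == 2L] > 120))
  expect_error(addInteractions(b1, minSupport = -1), "minSupport")
})

test_that("bin2 column count matches a brute-force pair enumeration", {
  rec <- fixRecords()[1:2000, ]
  b1 <- encodeBin1(rec)
  ms <- 150L
  b2 <- addInteractions(b1, minSupport = ms)
  cd1 <- featureColumns(b1)
  X1 <- featureValues(b1)
  seqIdx <- which(cd1$source %in% c("protein_seq", "target_seq"))
  sup <- Matrix::colSums(X1[, seqIdx] != 0)
  elig <- seqIdx[sup > ms]
  cnt <- 0L
  for (a in seq_along(elig)) for (b in seq_len(a - 1L)) {
    i <- elig[b]; j <- elig[a]
    if (cd1$position[i] == cd1$position[j]) next
    srcs <- sort(cd1$source[c(i, j)])
    if (identical(srcs, c("target_seq", "target_seq"))) next
    if (sum(X1[, i] * X1[, j]) > 0) cnt <- cnt + 1L
  }
  expect_identical(sum(featureColumns(b2)$order == 2L), cnt)
})

test_that("order-2 metadata partitions into M2M/M2T and intra/cross", {
  cd <- featureColumns(fixBin2())
  o2 <- cd[cd$order == 2L, ]
  expect_true(all(o2$iclass %in% c("M2M", "M2T")))
  expect_true(all(o2$module_side %in% c("p5N3", "p11N4", "cross")))
  m2t <- o2[o2$iclass == "M2T", ]
  expect_true(all(xor(grepl("^T", m2t$parent1), grepl("^T", m2t$parent2))))
  m2m <- o2[o2$iclass == "M2M", ]
  expect_true(all(grepl("^P", m2m$parent1) & grepl("^P", m2m$parent2)))
})

test_that("the feature-group algebra is closed and consistent", {
  b2 <- fixBin2()
  nm <- function(g) featureColumns(selectGroup(b2, g))$name
  expect_identical(length(nm("Mact")), 2L)
  expect_setequal(nm("SM-5_11"), union(nm("SM-5"), nm("SM-11")))
  expect_true(all(union(nm("SM-M2M"), nm("SM-M2T")) %in% nm("SeqMact")))
  expect_true(all(nm("SM-5_11") %in% nm("SM-M2M")))
  intra2 <- setdiff(nm("SM-Intra"), nm("SM-5_11"))
  cross2 <- setdiff(nm("SM-Cross"), nm("SM-5_11"))
  expect_length(intersect(intra2, cross2), 0)
  expect_setequal(nm("SeqMact"),
                  union(union(nm("SM-M2M"), nm("SM-M2T")), nm("SM-5_11")))
  expect_error(selectGroup(b2, "SM-bogus"), "unknown feature group")
})

test_that("encodeLike rebuilds the training design exactly", {
  rec <- fixRecords()[1:1500, ]
  b2 <- addInteractions(encodeBin1(rec), minSupport = 100)
  again <- encodeLike(rec, b2)
  expect_identical(featureColumns(again), featureColumns(b2))
  expect_equal(max(abs(featureValues(again) - featureValues(b2))), 0)
})
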