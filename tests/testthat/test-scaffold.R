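# Target geometry: region slicing, palindrome construction, distances.

test_that("region extraction slices the fixed coordinates", {
  t <- buildPalindrome("GTTGAGCTA", center2 = "AC")
  expect_identical(nchar(t), 22L)
  r <- extractRegions(t)
  expect_identical(r$r2N4, "GTAC")
  expect_identical(r$r5N3, "GTT")
  expect_identical(r$r7N2, "GA")
  expect_identical(r$r11N4, "GCTA")
  # pseudopalindrome symmetry: the reverse complement decomposes identically
  expect_identical(extractRegions(revComp(t))[-1], r[-1])
  expect_identical(revComp("GTAC"), "GTAC")
  expect_error(extractRegions("GTACN"), "length|alphabet")
  expect_error(extractRegions(paste(rep("N", 22), collapse = "")), "alphabet")
})

test_that("palindrome construction round-trips and is deterministic", {
  t <- buildPalindrome("GTTGAGCTA", center2 = "AC")
  expect_true(isPseudopalindromic(t))
  expect_identical(substr(t, 1, 11), revComp(substr(t, 12, 22)))
  r <- extractRegions(t)
  expect_identical(targetFromRegions(r$r5N3, r$r11N4, r$r7N2), t)
  expect_identical(buildPalindrome("GTTGAGCTA", "AC"),
                   buildPalindrome("GTTGAGCTA", "AC"))
  # 11-base form agrees with 9-base + center form
  expect_identical(buildPalindrome("ACGTTGAGCTA"), t)
  expect_error(buildPalindrome("GTTGAGCTA"), "center2")
  expect_error(buildPalindrome("GTTGAG", "AC"), "bases")
})

test_that("non-palindromic targets reduce to two valid palindromes", {
  set.seed(1)
  for (i in 1:10) {
    t <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
               collapse = "")
    both <- reduceToPalindromes(t)
    expect_true(all(isPseudopalindromic(both)))
    # left-derived output equals the palindrome built from revComp(left half)
    # treated as a right half (string-manipulation oracle)
    L <- substr(t, 1, 11)
    expect_identical(unname(both["left"]), paste0(L, revComp(L)))
    expect_identical(unname(both["right"]),
                     buildPalindrome(substr(t, 12, 22)))
  }
  wt <- wtTarget()
  expect_identical(unname(reduceToPalindromes(wt)), c(wt, wt))
})

test_that("target distance is a metric on the modeled regions", {
  t1 <- targetFromRegions("GTT", "GCTA")
  t2 <- targetFromRegions("GTA", "GCTA")
  expect_identical(targetDistance(t1, t1), 0L)
  expect_identical(targetDistance(t1, t2), 1L)
  set.seed(2)
  space5 <- enumerateRegionSpace("5N3")
  space11 <- enumerateRegionSpace("11N4")
  ts <- targetFromRegions(sample(space5, 30, TRUE), sample(space11, 30, TRUE))
  i <- sample(30, 20, TRUE); j <- sample(30, 20, TRUE); k <- sample(30, 20, TRUE)
  dij <- targetDistance(ts[i], ts[j])
  dji <- targetDistance(ts[j], ts[i])
  expect_identical(dij, dji)
  expect_true(all(dij <= targetDistance(ts[i], ts[k]) +
                    targetDistance(ts[k], ts[j])))
  # brute-force oracle on the concatenated modeled regions
  key <- function(t) paste0(extractRegions(t)$r11N4, extractRegions(t)$r5N3)
  oracle <- mapply(function(a, b)
    sum(strsplit(key(a), "")[[1]] != strsplit(key(b), "")[[1]]),
    ts[i], ts[j])
  expect_identical(dij, as.integer(unname(oracle)))
  expect_identical(targetDistance(t1, t2, scope = "full"),
                   as.integer(sum(strsplit(t1, "")[[1]] != strsplit(t2, "")[[1]])))
})

test_that("region spaces enumerate completely and in order", {
  s5 <- enumerateRegionSpace("5N3")
  s11 <- enumerateRegionSpace("11N4")
  expect_length(s5, 64)
  expect_length(s11, 256)
  expect_identical(anyDuplicated(s5), 0L)
  expect_identical(anyDuplicated(s11), 0L)
  expect_identical(s5[1], "AAA")
  expect_identical(s5[64], "TTT")
  expect_identical(s11[1], "AAAA")
  expect_identical(s11[256], "TTTT")
  expect_false(is.unsorted(s5))
  expect_error(enumerateRegionSpace("7N2"))
})

test_that("GTAC substitution and the reference target behave", {
  wt <- wtTarget()
  expect_true(isPseudopalindromic(wt))
  expect_identical(extractRegions(wt)$r2N4, "GTAC")
  t <- reduceToPalindromes(paste(rep(c("A", "C"), 11), collapse = ""))[["left"]]
  g <- gtacSubstitute(t)
  expect_identical(extractRegions(g)$r2N4, "GTAC")
  expect_identical(substr(g, 1, 9), substr(t, 1, 9))
  expect_identical(substr(g, 14, 22), substr(t, 14, 22))
})
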