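# Shared fixtures, built once per test run and memoized. Sizes are kept small
# (8 screening targets) so module tests stay fast; acceptance tests build
# their own, larger datasets.

.fixtures <- new.env(parent = emptyenv())

fixModel <- function() {
  if (is.null(.fixtures$model))
    .fixtures$model <- groundTruthModel(seed = 101)
  .fixtures$model
}

fixDataset <- function() {
  if (is.null(.fixtures$dataset))
    .fixtures$dataset <- generateScreeningDataset(fixModel(), nTargets = 8,
                                                  seed = 101)
  .fixtures$dataset
}

fixRecords <- function() screeningRecords(fixDataset())

fixBin1 <- function() {
  if (is.null(.fixtures$bin1)) .fixtures$bin1 <- encodeBin1(fixRecords())
  .fixtures$bin1
}

fixBin2 <- function() {
  if (is.null(.fixtures$bin2))
    .fixtures$bin2 <- addInteractions(fixBin1(), minSupport = 200)
  .fixtures$bin2
}

# hand-built records table with full control over residues/targets; all
# required screening columns present
makeRecords <- function(p44, p77 = NULL, p30 = NULL, r5N3 = "GTT",
                        r11N4 = "GCTA", label = NULL, act5 = 0.5,
                        act11 = 0.5) {
  n <- length(p44)
  rec <- data.frame(
    target = targetFromRegions(rep_len(r5N3, n), rep_len(r11N4, n)),
    r5N3 = rep_len(r5N3, n), r11N4 = rep_len(r11N4, n),
    p30 = if (is.null(p30)) "N" else p30, p32 = "S", p33 = "Y", p38 = "Q",
    p40 = "S", p44 = p44, p68 = "R", p70 = "R", p75 = "D",
    p77 = if (is.null(p77)) "I" else p77,
    p5_module = "m5", p11_module = "m11",
    act5 = act5, act11 = act11,
    activity = 0, label = if (is.null(label)) 0L else as.integer(label),
    measured = FALSE, stringsAsFactors = FALSE)
  rec$variant_id <- do.call(paste, c(lapply(c(30, 32, 33, 38, 40, 44, 68, 70,
                                              75, 77), function(p)
    paste0(p, rec[[paste0("p", p)]])), list(sep = "/")))
  rec
}

# brute-force AUC oracle: explicit loop over all positive-negative pairs
bruteForceAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
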