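## Target coordinate system.
##
## A target is a 22 bp site indexed -11..-1, +1..+11 (no position 0). In
## string coordinates (1..22) the regions are:
##   -11N4 = 1..4, -7N2 = 5..6, -5N3 = 7..9,
##   2N4   = 10..13 (positions -2,-1,+1,+2),
##   5N3   = 14..16 (+3..+5), 7N2 = 17..18 (+6,+7), 11N4 = 19..22 (+8..+11).
## In a pseudopalindrome the minus-side regions are the reverse complements of
## the plus-side ones, so the site is fully described by the right half plus
## the central 2N4.

REGION_COORDS <- list(
  r2N4  = c(10L, 13L),
  r5N3  = c(14L, 16L),
  r7N2  = c(17L, 18L),
  r11N4 = c(19L, 22L)
)

REGION_LENGTHS <- c("5N3" = 3L, "11N4" = 4L)

#' Test whether 22-mer targets are pseudopalindromic
#'
#' A target is pseudopalindromic when its full sequence equals its own reverse
#' complement apart from the central 2N4, i.e. the minus-half regions are the
#' reverse complements of the plus-half regions. With a reverse-complement
#' symmetric 2N4 (such as GTAC) the whole 22-mer equals its reverse
#' complement.
#'
#' @param targets character vector of 22-base DNA strings.
#' @return logical vector.
#' @export
isPseudopalindromic <- function(targets) {
  targets <- assertDna(targets, len = 22L)
  left <- substr(targets, 1L, 9L)
  right <- substr(targets, 14L, 22L)
  left == revComp(right)
}

#' Decompose targets into named regions
#'
#' Slices the fixed region coordinates of the 22 bp site: the central 2N4
#' (positions -2..+2 excluding 0), and the plus-half 5N3 (+3..+5), 7N2
#' (+6,+7) and 11N4 (+8..+11) regions. Pure positional slicing; the minus
#' half of a pseudopalindrome carries no extra information.
#'
#' @param targets character vector of 22-base DNA strings.
#' @return data.frame with columns `full`, `r2N4`, `r5N3`, `r7N2`, `r11N4`.
#' @examples
#' extractRegions(wtTarget())
#' @export
extractRegions <- function(targets) {
  targets <- assertDna(targets, len = 22L)
  out <- data.frame(full = targets, stringsAsFactors = FALSE)
  for (r in names(REGION_COORDS)) {
    co <- REGION_COORDS[[r]]
    out[[r]] <- substr(targets, co[1L], co[2L])
  }
  out
}

#' Build a pseudopalindromic target from its right half
#'
#' The full site is `revComp(right half) + right half` where the right half
#' consists of positions +1..+11. The half may be given either as the full
#' 11-mer, or as the 9-mer +3..+11 together with `center2` (positions +1,+2;
#' "AC" yields the GTAC 2N4).
#'
#' @param half 11-base right half, or 9-base +3..+11 part.
#' @param center2 2-base +1,+2 sequence, required when `half` has 9 bases.
#' @return 22-base pseudopalindromic target string(s).
#' @examples
#' buildPalindrome("GTTGAGCTA", center2 = "AC")
#' @export
buildPalindrome <- function(half, center2 = NULL) {
  half <- assertDna(half)
  n <- unique(nchar(half))
  if (length(n) != 1L) stop("mixed half lengths", call. = FALSE)
  if (n == 9L) {
    if (is.null(center2)) stop("center2 required with a 9-base half", call. = FALSE)
    center2 <- assertDna(center2, len = 2L)
    half <- paste0(center2, half)
  } else if (n != 11L) {
    stop("half must have 9 (+3..+11) or 11 (+1..+11) bases", call. = FALSE)
  } else if (!is.null(center2)) {
    stop("center2 must be omitted when half already has 11 bases", call. = FALSE)
  }
  paste0(revComp(half), half)
}

#' Reduce a (possibly non-palindromic) target to two pseudopalindromes
#'
#' A non-palindromic 22-mer is handled by designing a separate homodimeric
#' variant for each half: the left-derived palindrome is
#' `left half + revComp(left half)` and the right-derived palindrome
#' `revComp(right half) + right half`. A pseudopalindromic input is a fixed
#' point: both outputs equal the input.
#'
#' @param target 22-base DNA string.
#' @return named character vector `c(left = ..., right = ...)`.
#' @export
reduceToPalindromes <- function(target) {
  target <- assertDna(target, len = 22L)
  if (length(target) != 1L) stop("one target at a time", call. = FALSE)
  left <- substr(target, 1L, 11L)
  right <- substr(target, 12L, 22L)
  c(left = paste0(left, revComp(left)),
    right = paste0(revComp(right), right))
}

#' Hamming distance between targets over selected regions
#'
#' Distance is computed on the concatenated scoped regions of the plus half;
#' the default scope is the modeled half-site regions 11N4 + 5N3 (7 bases).
#' Use `scope = "full"` for the whole 22-mer.
#'
#' @param t1,t2 22-base DNA strings (vectors recycled to a common length).
#' @param scope character vector of region names among `"r5N3"`, `"r7N2"`,
#'   `"r11N4"`, `"r2N4"`, or the single value `"full"`.
#' @return integer vector of Hamming distances.
#' @export
targetDistance <- function(t1, t2, scope = c("r11N4", "r5N3")) {
  n <- max(length(t1), length(t2))
  t1 <- rep_len(assertDna(t1, 22L), n)
  t2 <- rep_len(assertDna(t2, 22L), n)
  if (identical(scope, "full")) return(as.integer(hammingStr(t1, t2)))
  if (!all(scope %in% names(REGION_COORDS)))
    stop("unknown region in scope", call. = FALSE)
  key <- function(t) {
    parts <- lapply(scope, function(r) {
      co <- REGION_COORDS[[r]]
      substr(t, co[1L], co[2L])
    })
    do.call(paste0, parts)
  }
  as.integer(hammingStr(key(t1), key(t2)))
}

#' Enumerate the full sequence space of a region
#'
#' All 4^len concrete DNA strings of the region, lexicographically sorted and
#' duplicate-free: 64 sequences for 5N3, 256 for 11N4.
#'
#' @param region `"5N3"` or `"11N4"`.
#' @return character vector of region sequences.
#' @examples
#' length(enumerateRegionSpace("5N3"))   # 64
#' length(enumerateRegionSpace("11N4"))  # 256
#' @export
enumerateRegionSpace <- function(region = c("5N3", "11N4")) {
  region <- match.arg(region)
  len <- REGION_LENGTHS[[region]]
  bases <- c("A", "C", "G", "T")
  grids <- rev(rep(list(bases), len))
  g <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  sort(do.call(paste0, g[rev(seq_len(len))]))
}

#' Substitute the central 2N4 region by GTAC
#'
#' GTAC is the 2N4 of the palindromic target derived from the left part of the
#' wild-type I-CreI site and one of the most cleavage-permissive centers; the
#' screening datasets are GTAC-centered, and the 2N4 region is excluded from
#' model features because its effect is independent of the other regions.
#'
#' @param targets 22-base DNA strings.
#' @return targets with positions -2..+2 replaced by `GTAC`.
#' @export
gtacSubstitute <- function(targets) {
  targets <- assertDna(targets, len = 22L)
  paste0(substr(targets, 1L, 9L), "GTAC", substr(targets, 14L, 22L))
}

#' Assemble a GTAC-centered pseudopalindromic target from region sequences
#'
#' Convenience constructor used by the simulator: the right half is
#' `AC + r5N3 + r7N2 + r11N4` (so the 2N4 is GTAC).
#'
#' @param r5N3 3-base 5N3 sequences.
#' @param r11N4 4-base 11N4 sequences.
#' @param r7N2 2-base 7N2 sequence (default the wild-type `GT`; the
#'   combinatorial process never varies its contacting residues).
#' @return 22-base target strings.
#' @export
targetFromRegions <- function(r5N3, r11N4, r7N2 = "GT") {
  r5N3 <- assertDna(r5N3, 3L); r11N4 <- assertDna(r11N4, 4L)
  r7N2 <- assertDna(r7N2, 2L)
  buildPalindrome(paste0(r5N3, r7N2, r11N4), center2 = "AC")
}
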