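## Interface geometry of the I-CreI homodimer.
##
## Each monomer reads one half of the 22 bp site. Residues 44, 68, 70, 75, 77
## contact the 5N3 region (positions +3..+5); residues 30, 32, 33, 38, 40
## contact the 11N4 region (positions +8..+11). The central 2N4 (positions
## -2..+2) makes no direct protein contact and is excluded from all model
## features.

#' Key interface positions of the p5N3 module half
#' @keywords internal
P5N3_POSITIONS <- c(44L, 68L, 70L, 75L, 77L)

#' Key interface positions of the p11N4 module half
#' @keywords internal
P11N4_POSITIONS <- c(30L, 32L, 33L, 38L, 40L)

#' All key interface positions, ascending
#' @keywords internal
KEY_POSITIONS <- sort(c(P5N3_POSITIONS, P11N4_POSITIONS))

## Wild-type residues at the key positions (Q44, R68, R70, D75, I77;
## N30, S32, Y33, Q38, S40).
WT_RESIDUES <- c(
  "30" = "N", "32" = "S", "33" = "Y", "38" = "Q", "40" = "S",
  "44" = "Q", "68" = "R", "70" = "R", "75" = "D", "77" = "I"
)

## Residue alphabets observed at each key position in engineered libraries.
## Wild type first; the sets include the mutations discussed in the feature
## analysis (44F, 32K, 44R, 77R).
DEFAULT_ALPHABETS <- list(
  "30" = c("N", "K", "R", "Q", "H", "D"),
  "32" = c("S", "K", "R", "T", "D", "N"),
  "33" = c("Y", "H", "R", "G", "S", "T"),
  "38" = c("Q", "A", "R", "Y", "N", "E"),
  "40" = c("S", "K", "R", "Q", "A", "N"),
  "44" = c("Q", "K", "N", "R", "A", "F"),
  "68" = c("R", "Y", "N", "S", "T", "A"),
  "70" = c("R", "S", "N", "K", "Q", "A"),
  "75" = c("D", "N", "E", "Q", "R", "V"),
  "77" = c("I", "R", "V", "K", "N", "T")
)

#' Reference wild-type I-CreI target site
#'
#' The palindromic GTAC-centered reference target derived from the left half
#' of the natural I-CreI site. The exact reference 22-mer is a configurable
#' convention, not a hard-coded assumption: set
#' `options(mndesign.wt_target = "...")` to override (the value must be a
#' valid pseudopalindromic 22-mer).
#'
#' @return A 22-character DNA string.
#' @examples
#' wtTarget()
#' @export
wtTarget <- function() {
  t <- getOption("mndesign.wt_target", "CAAAACGTCGTACGACGTTTTG")
  assertDna(t, len = 22L)
  if (!isPseudopalindromic(t))
    stop("configured wild-type target is not pseudopalindromic", call. = FALSE)
  t
}

#' Wild-type residues at the key interface positions
#'
#' @return Named character vector (names are residue positions 30..77).
#' @export
wtResidues <- function() WT_RESIDUES
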