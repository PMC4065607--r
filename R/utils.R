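## Internal helpers shared across modules.

#' Validate a DNA string vector over the strict {A,C,G,T} alphabet
#'
#' Degenerate/IUPAC bases are rejected: screening data carry concrete
#' sequences only.
#' @param x character vector.
#' @param len required length of every element, or NULL to skip.
#' @return x, invisibly, uppercased.
#' @keywords internal
assertDna <- function(x, len = NULL) {
  if (!is.character(x) || anyNA(x))
    stop("DNA input must be a character vector without NA", call. = FALSE)
  x <- toupper(x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop("invalid DNA alphabet (only A/C/G/T allowed): ",
         paste(head(x[bad], 3L), collapse = ", "), call. = FALSE)
  if (!is.null(len) && any(nchar(x) != len))
    stop("DNA string must have length ", len, call. = FALSE)
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of A/C/G/T strings.
#' @return character vector of reverse complements.
#' @examples
#' revComp("GTAC")  # "GTAC": the GTAC center is its own reverse complement
#' @export
revComp <- function(x) {
  x <- toupper(x)
  assertDna(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## clip to [0, 1]
clip01 <- function(x) pmin(pmax(x, 0), 1)

## Hamming distance between two equal-length strings (vectorized over pairs)
hammingStr <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- nchar(a)
  if (any(nchar(b) != n)) stop("hamming distance needs equal-length strings")
  m1 <- matrix(unlist(strsplit(a, "", fixed = TRUE)), ncol = length(a))
  m2 <- matrix(unlist(strsplit(b, "", fixed = TRUE)), ncol = length(b))
  colSums(m1 != m2)
}

## Hamming distances from one string to a vector of strings of equal length
hammingTo <- function(s, xs) {
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  m <- matrix(unlist(strsplit(xs, "", fixed = TRUE)), nrow = nchar(s))
  colSums(m != sv)
}

## Deterministic variant id from a named residue vector.
## Format: "30N/32S/.../77I" with positions ascending.
variantId <- function(residues) {
  pos <- as.character(KEY_POSITIONS)
  paste0(pos, residues[pos], collapse = "/")
}

## Derive a reproducible child seed from a master seed and an offset.
## Kept below 2^31 so it is always a valid R integer.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1003L + offset * 7919) %% 2147483629)
}

## condition constructors used by the CLI for exit-code mapping
usageError <- function(msg) {
  structure(class = c("mn_usage_error", "error", "condition"),
            list(message = msg, call = NULL))
}
validationError <- function(msg) {
  structure(class = c("mn_validation_error", "error", "condition"),
            list(message = msg, call = NULL))
}
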