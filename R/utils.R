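DNA_BASES <- c("A", "C", "G", "T")

#' Encode a DNA string as integer codes
#'
#' A/C/G/T map to 1..4; any other character (N, IUPAC ambiguity codes)
#' maps to 5, which the scanner treats as unmatchable.
#'
#' @param x a single character string over the DNA alphabet.
#' @return integer vector of codes, one per base.
#' @keywords internal
#' @noRd
encode_dna <- function(x) {
  codes <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_BASES)
  codes[is.na(codes)] <- 5L
  as.integer(codes)
}

#' Reverse complement of a DNA character string
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp_dna("ACGTN")
revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reverse complement on integer codes (1..4 bases, 5 = N)
revcomp_codes <- function(codes) {
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rev(comp[codes])
}

# message() wrapper so pipeline logging can be silenced uniformly
esdeg_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}
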