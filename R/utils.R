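## Small shared helpers. Internal coordinates are always 0-based half-open
## genomic intervals; GTF I/O converts to/from 1-based inclusive.

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Hamming distance between two equal-length strings
#'
#' @param a,b character scalars of equal length.
#' @return integer number of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): unequal lengths")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## distance from a point to a half-open interval [s, e); 0 when inside
.point_interval_dist <- function(p, s, e) {
  pmax(pmax(s - p, p - (e - 1L)), 0L)
}

## random DNA of length n (uses current RNG stream)
.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## the 61 non-stop codons
.sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  cod <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(cod, c("TAA", "TAG", "TGA"))
}

## stop codons in all three frames (12 nt)
.stop_tail <- function() "TAAATAAATAAA"

.is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
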