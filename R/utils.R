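# Internal string helpers shared across modules.

#' Reverse complement of DNA strings
#'
#' Vectorised wrapper around [Biostrings::reverseComplement()] that accepts
#' and returns plain character vectors (IUPAC codes allowed).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Number of mismatches between each string in `x` and a single `pattern`,
# compared over positions `at` .. `at + nchar(pattern) - 1` of `x`.
# Positions beyond the end of a string count as mismatches.
.mismatches_to <- function(x, pattern, at = 1L) {
  n <- nchar(pattern)
  mm <- integer(length(x))
  for (j in seq_len(n)) {
    pj <- substr(pattern, j, j)
    xj <- substr(x, at + j - 1L, at + j - 1L)
    mm <- mm + (xj != pj)
  }
  mm
}

# Phred score characters (offset 33) -> integer matrix-free list of scores.
.qual_to_phred <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

.phred_to_qual <- function(scores) {
  vapply(scores, function(s) intToUtf8(s + 33L), character(1))
}

.assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside A,C,G,T,N (first offender: %s)",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}
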