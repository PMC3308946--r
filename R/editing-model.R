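# Editing-site combinatorics: the five editable adenosines A, B, E, C, D of
# the 5-HT2C cassette, the 32 editing codes they generate, and the mapping to
# nucleotide patterns and predicted protein triplets.

# Character positions of the five sites inside the 19-character display
# pattern "AnB-nnn-ECn-nnn-Dnn".
.PATTERN_POS <- c(A = 1L, B = 3L, E = 9L, C = 10L, D = 17L)
.PATTERN_TEMPLATE <- "nnn-nnn-nnn-nnn-nnn"

#' Normalise an editing-code representation
#'
#' An editing code is the 5-bit edited/unedited state of sites A, B, E, C, D.
#' It can be given either as a logical vector of length 5 (in site order
#' A, B, E, C, D) or as a string of edited-site letters such as `"ABD"`
#' (`""` or `"-"` for the unedited code).
#'
#' @param code logical vector of length 5, or a site-letter string.
#' @return named logical vector with elements `A, B, E, C, D`.
#' @export
#' @examples
#' as_editing_code("ABD")
#' as_editing_code(c(TRUE, FALSE, FALSE, FALSE, TRUE))
as_editing_code <- function(code) {
  if (is.logical(code)) {
    stopifnot(length(code) == 5L, !anyNA(code))
    names(code) <- EDIT_SITES
    return(code)
  }
  if (is.character(code) && length(code) == 1L) {
    if (code %in% c("", "-")) return(setNames(rep(FALSE, 5L), EDIT_SITES))
    letters <- strsplit(code, "")[[1]]
    if (!all(letters %in% EDIT_SITES) || anyDuplicated(letters)) {
      stop("invalid edited-site string: ", code, call. = FALSE)
    }
    return(setNames(EDIT_SITES %in% letters, EDIT_SITES))
  }
  stop("editing code must be a 5-element logical vector or a site string",
       call. = FALSE)
}

#' Edited-site string of a code
#'
#' @param code an editing code (see [as_editing_code()]).
#' @return string of edited site letters in A, B, E, C, D order (`""` if
#'   unedited).
#' @export
sites_of_code <- function(code) {
  code <- as_editing_code(code)
  paste(EDIT_SITES[code], collapse = "")
}

#' Enumerate all 32 editing codes
#'
#' Returns every edited/unedited combination of the five cassette sites in
#' canonical order: lexicographic over (A, B, E, C, D) with unedited (FALSE)
#' before edited (TRUE), so the fully unedited code comes first and the fully
#' edited code (ABECD) last.
#'
#' @return data frame with 32 rows and logical columns `A, B, E, C, D` plus a
#'   character column `sites` (edited-site string).
#' @export
#' @examples
#' codes <- enumerate_codes()
#' nrow(codes)          # 32
#' codes$sites[c(1, 32)]
enumerate_codes <- function() {
  g <- expand.grid(D = c(FALSE, TRUE), C = c(FALSE, TRUE), E = c(FALSE, TRUE),
                   B = c(FALSE, TRUE), A = c(FALSE, TRUE),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, EDIT_SITES]
  g$sites <- apply(g[, EDIT_SITES], 1L, function(r) paste(EDIT_SITES[r], collapse = ""))
  rownames(g) <- NULL
  g
}

#' Translate an editing code to its predicted protein triplet
#'
#' The five sites fall in three codons of the cassette reading frame: sites A
#' and B at positions 1 and 3 of an ATA (Ile) codon, sites E and C at
#' positions 1 and 2 of an AAT (Asn) codon two codons downstream, and site D
#' at position 1 of the following ATT (Ile) codon.  An edited site is read as
#' G; the three affected codons are translated with the standard genetic code
#' and reported as a three-letter string, e.g. `"INI"` (unedited) or `"VGV"`
#' (fully edited).
#'
#' @param code an editing code, or a character vector of edited-site strings
#'   (vectorised).
#' @param ref cassette reference giving the codon context
#'   (default [default_reference()]).
#' @return character vector of amino-acid triplets.
#' @export
#' @examples
#' translate_code("")       # "INI"
#' translate_code("ABD")    # "VNV"
#' translate_code("ABECD")  # "VGV"
translate_code <- function(code, ref = default_reference()) {
  if (is.character(code) && length(code) > 1L) {
    return(vapply(code, translate_code, character(1), ref = ref, USE.NAMES = FALSE))
  }
  code <- as_editing_code(code)
  seq <- ref$sequence
  for (s in EDIT_SITES[code]) {
    pos <- ref$site_offsets[[s]]
    substr(seq, pos, pos) <- "G"
  }
  f <- ref$frame_offset
  n_codons <- (nchar(seq) - f + 1L) %/% 3L
  starts <- f + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  # codons containing at least one editable site, in frame order
  site_pos <- sort(unlist(ref$site_offsets))
  affected <- vapply(starts, function(s) any(site_pos >= s & site_pos <= s + 2L), logical(1))
  aa <- Biostrings::GENETIC_CODE[codons[affected]]
  paste(aa, collapse = "")
}

#' Number of distinct predicted proteins over all editing codes
#'
#' Translates every enumerated code and counts distinct amino-acid triplets.
#' The 32 mRNA editing isoforms collapse to 24 proteins because the A/B codon
#' encodes valine for three of its four states.
#'
#' @inheritParams translate_code
#' @return integer count of distinct protein triplets.
#' @export
#' @examples
#' count_distinct_proteins()  # 24
count_distinct_proteins <- function(ref = default_reference()) {
  length(unique(translate_code(enumerate_codes()$sites, ref = ref)))
}

#' Render an editing code as a display pattern
#'
#' Produces the 19-character dash-delimited nucleotide pattern used in
#' isoform tables (header `AnB-nnn-ECn-nnn-Dnn`): the five site positions
#' carry `A` (unedited) or `G` (edited) and every other position is `n`.
#'
#' @param code an editing code, or a character vector of edited-site strings
#'   (vectorised).
#' @return character vector of patterns, e.g. `"GnG-nnn-AAn-nnn-Gnn"` for the
#'   ABD-edited code.
#' @export
pattern_for_code <- function(code) {
  if (is.character(code) && length(code) > 1L) {
    return(vapply(code, pattern_for_code, character(1), USE.NAMES = FALSE))
  }
  code <- as_editing_code(code)
  pat <- .PATTERN_TEMPLATE
  for (s in EDIT_SITES) {
    p <- .PATTERN_POS[[s]]
    substr(pat, p, p) <- if (code[[s]]) "G" else "A"
  }
  pat
}

#' Parse a display pattern back to an editing code
#'
#' Inverse of [pattern_for_code()]; rejects strings of the wrong length, with
#' misplaced dashes, or with a base other than A/G at a site position.
#'
#' @param pattern a 19-character pattern string.
#' @return named logical editing code.
#' @export
parse_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  if (nchar(pattern) != 19L) {
    stop("pattern must be 19 characters, got ", nchar(pattern), call. = FALSE)
  }
  if (!identical(which(strsplit(pattern, "")[[1]] == "-"),
                 c(4L, 8L, 12L, 16L))) {
    stop("pattern dashes must sit at positions 4, 8, 12, 16", call. = FALSE)
  }
  calls <- vapply(EDIT_SITES,
                  function(s) substr(pattern, .PATTERN_POS[[s]], .PATTERN_POS[[s]]),
                  character(1))
  if (!all(calls %in% c("A", "G"))) {
    stop("site positions must carry A or G", call. = FALSE)
  }
  setNames(calls == "G", EDIT_SITES)
}

#' Human-readable isoform label for a code
#'
#' @param code an editing code, or a character vector of edited-site strings.
#' @return e.g. `"ABD edited form"`, or `"UNEDITED"` for the unedited code.
#' @export
isoform_label <- function(code) {
  if (is.character(code) && length(code) > 1L) {
    return(vapply(code, isoform_label, character(1), USE.NAMES = FALSE))
  }
  s <- sites_of_code(code)
  if (s == "") "UNEDITED" else paste(s, "edited form")
}

#' Construct a cassette reference
#'
#' The cassette reference anchors site calling: the unedited sense-strand
#' sequence of the editing region, the 1-based offsets of the five editable
#' adenosines within it, and the position where the cassette reading frame
#' begins.  Optional flanking sequences are used only by the read simulator
#' to build full-length amplicons.
#'
#' @param sequence unedited sense-strand sequence containing the editing
#'   region.
#' @param site_offsets named integer vector (`A, B, E, C, D`) of 1-based site
#'   positions within `sequence`; must be strictly increasing.
#' @param frame_offset 1-based position where the first cassette codon begins.
#' @param amplicon_flank5,amplicon_flank3 optional flanking sequences between
#'   the PCR primers and the editing region (simulator only).
#' @return object of class `cassette_reference`.
#' @export
cassette_reference <- function(sequence, site_offsets, frame_offset,
                               amplicon_flank5 = "", amplicon_flank3 = "") {
  sequence <- toupper(sequence)
  .assert_dna(sequence, "reference sequence")
  stopifnot(identical(names(site_offsets), EDIT_SITES))
  site_offsets <- as.integer(site_offsets)
  names(site_offsets) <- EDIT_SITES
  if (any(site_offsets < 1L) || any(site_offsets > nchar(sequence))) {
    stop("site offsets outside reference sequence", call. = FALSE)
  }
  if (any(diff(site_offsets) <= 0L)) {
    stop("site offsets must be strictly increasing in A < B < E < C < D order",
         call. = FALSE)
  }
  at_sites <- substring(sequence, site_offsets, site_offsets)
  if (!all(at_sites == "A")) {
    stop("reference must be unedited: base at every site offset must be A",
         call. = FALSE)
  }
  # frame consistency: A/B at codon positions 1/3, E/C at 1/2 two codons
  # downstream, D at position 1 two codons after that (one untouched codon
  # sits between the E/C codon and the D codon, as in the display pattern
  # ECn-nnn-Dnn)
  cpos <- (site_offsets - frame_offset) %% 3L + 1L
  codon <- (site_offsets - frame_offset) %/% 3L
  ok <- identical(unname(cpos), c(1L, 3L, 1L, 2L, 1L)) &&
    codon[["A"]] == codon[["B"]] &&
    codon[["E"]] == codon[["A"]] + 2L && codon[["C"]] == codon[["E"]] &&
    codon[["D"]] == codon[["E"]] + 2L
  if (!ok) stop("site offsets inconsistent with the cassette reading frame",
                call. = FALSE)
  structure(list(sequence = sequence,
                 site_offsets = site_offsets,
                 frame_offset = as.integer(frame_offset),
                 amplicon_flank5 = toupper(amplicon_flank5),
                 amplicon_flank3 = toupper(amplicon_flank3)),
            class = "cassette_reference")
}

# Fixed filler flanks used by the simulator to pad the cassette out to a
# ~300 bp amplicon between the PCR primers.  Arbitrary non-homopolymeric
# sequence chosen once; contains no secondary match to the degenerate
# cassette core in either orientation.
.FLANK5 <- "CCCAACATAAACTTTCCTTAACATTAATTTCCGACCACAATCTCCTGAGCTGTGGTAATCTGAACCATGGGTCGTGGGTGAGTTCGTT"
.FLANK3 <- "CCTTCCTCTTATCTGAGAATTTCTAAGGCATTCAGTCGGCTAACGTGCTGTATTCCCGGGTTATACACCGGCGGCGGGCACCCGTGTG"

#' Built-in 5-HT2C cassette reference
#'
#' The 21-nt unedited core `TAGCAATACGTAATCCTATTG` with site offsets
#' A=6, B=8, E=12, C=13, D=18 and reading frame starting at position 6
#' (codons ATA, CGT, AAT, CCT, ATT).  The core is the interior of the
#' unedited (INI) isoform hydrolysis probe; substituting G at the edited
#' sites of any isoform reproduces the corresponding edited-isoform probe at
#' all five site positions.
#'
#' @return a [cassette_reference()] object.
#' @export
#' @examples
#' ref <- default_reference()
#' substring(ref$sequence, ref$site_offsets, ref$site_offsets)  # all "A"
default_reference <- function() {
  cassette_reference(
    sequence = "TAGCAATACGTAATCCTATTG",
    site_offsets = c(A = 6L, B = 8L, E = 12L, C = 13L, D = 18L),
    frame_offset = 6L,
    amplicon_flank5 = .FLANK5,
    amplicon_flank3 = .FLANK3
  )
}

#' @export
print.cassette_reference <- function(x, ...) {
  cat("cassette_reference\n")
  cat("  sequence:    ", x$sequence, " (", nchar(x$sequence), " nt)\n", sep = "")
  cat("  sites:       ",
      paste(sprintf("%s=%d", names(x$site_offsets), x$site_offsets), collapse = " "),
      "\n", sep = "")
  cat("  frame start: ", x$frame_offset, "\n", sep = "")
  invisible(x)
}

#' Packaged 32-row isoform taxonomy
#'
#' The full isoform taxonomy of the cassette: isoform label, display
#' pattern, protein triplet and edited-site set for each of the 32 editing
#' codes, shipped as a TSV under `inst/extdata`.
#'
#' @return data frame with columns `label`, `pattern`, `protein`,
#'   `edited_sites` (32 rows).
#' @export
isoform_taxonomy <- function() {
  path <- system.file("extdata", "isoform_taxonomy.tsv", package = "edcas",
                      mustWork = TRUE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$edited_sites[is.na(tab$edited_sites) | tab$edited_sites == "-"] <- ""
  tab
}
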