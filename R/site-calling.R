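# Per-read calling of the five editing sites.  Each trimmed, sense-oriented
# read is located against the unedited cassette reference; the base over
# each site offset is read as unedited (A), edited (G) or ambiguous
# (anything else, including gaps).
#
# Two paths produce identical calls:
#  * a fast vectorised path that locates the cassette core with a degenerate
#    pattern (A/G wildcards at the five sites) and indexes the read directly
#    -- valid whenever the cassette region carries no indel;
#  * a per-read glocal (pattern-global, subject-local) affine-gap alignment
#    fallback for reads the fast path cannot place.

#' Alignment parameters for site calling
#'
#' @param match,mismatch substitution scores (match > 0 >= mismatch).
#' @param gap_open,gap_extend affine gap penalties (<= 0).
#' @param min_identity minimum identity over the aligned cassette span,
#'   computed over non-site positions only -- mismatches at the five
#'   editable sites are biology, not sequencing error, and do not count
#'   against a read.
#' @return object of class `alignment_params`.
#' @export
alignment_params <- function(match = 2, mismatch = -1, gap_open = -4,
                             gap_extend = -1, min_identity = 0.8) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0,
            min_identity > 0, min_identity <= 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity = min_identity),
            class = "alignment_params")
}

# Degenerate cassette core: R (A/G) at the five site offsets.
.degenerate_core <- function(ref) {
  core <- ref$sequence
  for (pos in ref$site_offsets) substr(core, pos, pos) <- "R"
  core
}

# Non-site mismatch budget implied by min_identity.
.mismatch_budget <- function(ref, p) {
  n_nonsite <- nchar(ref$sequence) - length(ref$site_offsets)
  floor((1 - p$min_identity) * n_nonsite)
}

#' Glocal alignment of a read to the cassette reference
#'
#' Aligns the reference sequence globally within the read (Needleman-Wunsch
#' with affine gaps; the read is consumed locally), producing a map from
#' every reference position to the corresponding read position or `NA` for a
#' gap.  The alignment is rejected when the non-site identity over the
#' aligned span falls below `p$min_identity` (reason `"identity"`) or when
#' the aligned span does not reach every site offset (reason `"span"`).
#'
#' @param sequence a single read sequence (character), sense-oriented.
#' @param ref a [cassette_reference()].
#' @param p an [alignment_params()].
#' @return list with `map` (integer vector, one entry per reference
#'   position), `identity`, `score`, `ok` (logical) and `reason`
#'   (`NA`, `"identity"` or `"span"`).
#' @export
align_to_reference <- function(sequence, ref, p = alignment_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("cannot align an empty read", call. = FALSE)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = p$match, mismatch = p$mismatch, baseOnly = FALSE)
  # ends-free alignment: the cassette may run off either end of a truncated
  # read, leaving uncovered reference positions unaligned rather than
  # force-matched
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ref$sequence),
    subject = Biostrings::DNAString(sequence),
    type = "overlap",
    substitutionMatrix = submat,
    gapOpening = -p$gap_open, gapExtension = -p$gap_extend)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  nref <- nchar(ref$sequence)
  map <- rep(NA_integer_, nref)
  ri <- IRanges::start(Biostrings::pattern(pa)) - 1L
  si <- IRanges::start(Biostrings::subject(pa)) - 1L
  for (k in seq_along(ap)) {
    if (as_[k] != "-") si <- si + 1L
    if (ap[k] != "-") {
      ri <- ri + 1L
      if (as_[k] != "-") map[ri] <- si
    }
  }
  site_pos <- unname(ref$site_offsets)
  nonsite <- setdiff(seq_len(nref), site_pos)
  aligned_nonsite <- nonsite[!is.na(map[nonsite])]
  matches <- sum(substring(sequence, map[aligned_nonsite], map[aligned_nonsite]) ==
                   substring(ref$sequence, aligned_nonsite, aligned_nonsite))
  identity <- if (length(aligned_nonsite) > 0L) matches / length(nonsite) else 0
  aligned_ref <- which(!is.na(map))
  span_ok <- length(aligned_ref) > 0L &&
    all(site_pos >= min(aligned_ref) & site_pos <= max(aligned_ref))
  reason <- NA_character_
  ok <- TRUE
  if (!span_ok) {
    ok <- FALSE; reason <- "span"
  } else if (identity < p$min_identity) {
    ok <- FALSE; reason <- "identity"
  }
  list(map = map, identity = identity, score = Biostrings::score(pa),
       ok = ok, reason = reason)
}

.call_from_bases <- function(bases) {
  ifelse(bases == "A", "unedited", ifelse(bases == "G", "edited", "ambiguous"))
}

.empty_calls <- function() {
  df <- data.frame(read_id = character(0), group = character(0),
                   stringsAsFactors = FALSE)
  for (s in EDIT_SITES) df[[s]] <- character(0)
  df$status <- character(0)
  df$reason <- character(0)
  df
}

#' Call the five editing sites on trimmed reads
#'
#' For each read, locates the cassette and reads the base over each site
#' offset: `A` -> unedited, `G` -> edited, anything else (C, T, N or a gap)
#' -> ambiguous.  A read is `classified` iff all five calls are unambiguous;
#' otherwise it is `rejected` with a reason (`"ambiguous"`, `"identity"` or
#' `"span"`).  Reads that cannot be placed by the fast degenerate-core
#' search fall back to [align_to_reference()].
#'
#' @param reads data frame with columns `id`, `sequence` and optionally
#'   `group` (carried through).
#' @param ref a [cassette_reference()].
#' @param p an [alignment_params()].
#' @return data frame with columns `read_id`, `group`, `A`, `B`, `E`, `C`,
#'   `D` (each `"unedited"`, `"edited"` or `"ambiguous"`), `status`
#'   (`"classified"`/`"rejected"`), `reason`.
#' @export
call_sites <- function(reads, ref = default_reference(), p = alignment_params()) {
  stopifnot(all(c("id", "sequence") %in% names(reads)))
  n <- nrow(reads)
  if (n == 0L) return(.empty_calls())
  group <- if ("group" %in% names(reads)) reads$group else rep(NA_character_, n)
  seqs <- toupper(reads$sequence)
  site_pos <- unname(ref$site_offsets)
  site_bases <- matrix(NA_character_, nrow = n, ncol = 5L,
                       dimnames = list(NULL, EDIT_SITES))
  reason <- rep(NA_character_, n)
  placed <- rep(FALSE, n)

  # fast path: locate the degenerate core allowing the non-site mismatch
  # budget; unique placement required
  deg <- .degenerate_core(ref)
  budget <- .mismatch_budget(ref, p)
  hits <- Biostrings::vmatchPattern(deg, Biostrings::DNAStringSet(seqs),
                                    max.mismatch = budget, fixed = FALSE)
  starts <- Biostrings::startIndex(hits)
  for (i in seq_len(n)) {
    st <- starts[[i]]
    if (length(st) == 1L) {
      placed[i] <- TRUE
      site_bases[i, ] <- substring(seqs[i], st + site_pos - 1L, st + site_pos - 1L)
    }
  }

  # fallback: glocal alignment for unplaced reads (indels, partial cores)
  for (i in which(!placed)) {
    al <- align_to_reference(seqs[i], ref, p)
    if (!al$ok) { reason[i] <- al$reason; next }
    placed[i] <- TRUE
    pos <- al$map[site_pos]
    b <- rep("-", 5L)
    b[!is.na(pos)] <- substring(seqs[i], pos[!is.na(pos)], pos[!is.na(pos)])
    site_bases[i, ] <- b
  }

  out <- data.frame(read_id = reads$id, group = group, stringsAsFactors = FALSE)
  for (s in EDIT_SITES) {
    out[[s]] <- ifelse(placed, .call_from_bases(site_bases[, s]), "ambiguous")
  }
  ambiguous <- !placed | apply(out[, EDIT_SITES] == "ambiguous", 1L, any)
  out$status <- ifelse(ambiguous, "rejected", "classified")
  out$reason <- ifelse(placed & ambiguous, "ambiguous", reason)
  out
}

#' Editing code of classified site calls
#'
#' @param calls data frame from [call_sites()]; every row must be
#'   classified.
#' @return character vector of edited-site strings (one per row), e.g.
#'   `""`, `"ABD"`, `"ABECD"`.
#' @export
code_of <- function(calls) {
  if (any(calls$status != "classified")) {
    stop("code_of() requires classified calls only; filter on status first",
         call. = FALSE)
  }
  m <- as.matrix(calls[, EDIT_SITES]) == "edited"
  apply(m, 1L, function(r) paste(EDIT_SITES[r], collapse = ""))
}
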