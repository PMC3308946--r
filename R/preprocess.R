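# Demultiplexing of pooled amplicon reads by adaptor+barcode, and the
# quality filter applying an average and an end error-probability threshold.

#' Demultiplexing configuration
#'
#' Describes the structure of a pooled amplicon read:
#' `adaptor + barcode + forward primer + insert + rc(reverse primer) +
#' rc(adaptor B)`, possibly reverse-complemented as a whole.  Defaults are
#' the 454-style library design used for the 5-HT2C cassette: adaptor A/B,
#' one 10-nt barcode per animal group (lean control and leptin-deficient
#' *ob/ob*), and the cassette PCR primer pair.
#'
#' @param adaptor_a,adaptor_b sequencing adaptors (A on the barcoded end).
#' @param barcodes named character vector, group name -> barcode sequence.
#' @param forward_primer,reverse_primer cassette PCR primers (sense strand).
#' @param max_barcode_mismatches maximum mismatches tolerated inside the
#'   barcode (default 1; the barcodes must stay unambiguous, i.e. every
#'   pairwise barcode Hamming distance must exceed twice this value).
#' @return object of class `demux_config`.
#' @export
demux_config <- function(adaptor_a = "CGTATCGCCTCCCTCGCGCCATCAG",
                         adaptor_b = "CTATGCGCCTTGCCAGCCCGCTCAG",
                         barcodes = c(lean = "ACGAGTGCGT",
                                      obob = "ACGCTCGACA"),
                         forward_primer = "TGCTGATATGCTGGTGGGACT",
                         reverse_primer = "TCGTCCCTCAGTCCAATCACAG",
                         max_barcode_mismatches = 1L) {
  stopifnot(length(barcodes) >= 1L, !is.null(names(barcodes)),
            all(nzchar(names(barcodes))))
  for (s in c(adaptor_a, adaptor_b, unname(barcodes),
              forward_primer, reverse_primer)) .assert_dna(toupper(s))
  barcodes <- toupper(barcodes)
  if (anyDuplicated(barcodes)) stop("barcodes must be distinct", call. = FALSE)
  if (length(unique(nchar(barcodes))) != 1L) {
    stop("barcodes must share one length", call. = FALSE)
  }
  max_barcode_mismatches <- as.integer(max_barcode_mismatches)
  if (length(barcodes) > 1L) {
    pairs <- utils::combn(seq_along(barcodes), 2L)
    dists <- apply(pairs, 2L, function(ij) {
      .mismatches_to(barcodes[ij[1]], barcodes[ij[2]])
    })
    if (any(dists <= 2L * max_barcode_mismatches)) {
      stop("barcode pair too close for the mismatch tolerance", call. = FALSE)
    }
  }
  structure(list(adaptor_a = toupper(adaptor_a),
                 adaptor_b = toupper(adaptor_b),
                 barcodes = barcodes,
                 forward_primer = toupper(forward_primer),
                 reverse_primer = toupper(reverse_primer),
                 max_barcode_mismatches = max_barcode_mismatches),
            class = "demux_config")
}

#' Quality-filter thresholds
#'
#' The filter accepts a read iff its mean per-base error probability does
#' not exceed `max_avg_error` and every base within `end_window` bases of
#' either end has error probability at most `max_end_error`.  Defaults are
#' the conventional amplicon-cleaning settings: average 0.025, ends 0.02
#' over the 2 terminal bases.
#'
#' @param max_avg_error maximum mean error probability per read.
#' @param max_end_error maximum per-base error probability at the read ends.
#' @param end_window number of bases checked at each end.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_avg_error = 0.025, max_end_error = 0.02,
                          end_window = 2L) {
  stopifnot(max_avg_error > 0, max_avg_error < 1,
            max_end_error > 0, max_end_error < 1, end_window >= 1L)
  structure(list(max_avg_error = max_avg_error,
                 max_end_error = max_end_error,
                 end_window = as.integer(end_window)),
            class = "qc_thresholds")
}

#' Phred score to error probability
#'
#' @param q numeric vector of Phred scores (>= 0).
#' @return error probabilities `10^(-q/10)`.
#' @export
#' @examples
#' phred_to_error(c(0, 20, 30))
phred_to_error <- function(q) {
  if (any(q < 0)) stop("Phred scores must be non-negative", call. = FALSE)
  10^(-q / 10)
}

# Demultiplex a block of same-orientation reads against one strand.
# Returns a list of vectors: group index (0 = unassigned), insert start/end.
.demux_one_strand <- function(seqs, cfg) {
  la <- nchar(cfg$adaptor_a)
  lb <- nchar(cfg$barcodes[[1]])
  lp <- nchar(cfg$forward_primer)
  n <- length(seqs)
  adaptor_mm <- .mismatches_to(seqs, cfg$adaptor_a, at = 1L)
  bc_mm <- vapply(cfg$barcodes, function(bc) {
    .mismatches_to(seqs, bc, at = la + 1L)
  }, integer(n))
  bc_mm <- matrix(bc_mm, nrow = n)
  best <- max.col(-bc_mm, ties.method = "first")
  best_mm <- bc_mm[cbind(seq_len(n), best)]
  # ambiguous when another barcode ties the best distance
  n_at_best <- rowSums(bc_mm == best_mm)
  primer_mm <- .mismatches_to(seqs, cfg$forward_primer, at = la + lb + 1L)
  ok <- adaptor_mm <= 1L &
    best_mm <= cfg$max_barcode_mismatches &
    n_at_best == 1L &
    primer_mm <= 1L
  list(group = ifelse(ok, best, 0L), insert_start = la + lb + lp + 1L)
}

#' Assign pooled reads to groups and trim them
#'
#' Searches each read (and its reverse complement) for the adaptor-A +
#' barcode + forward-primer prefix: the adaptor is anchored at the read
#' start with at most one mismatch, the barcode must be within
#' `max_barcode_mismatches` of exactly one configured barcode, and the
#' forward primer must follow with at most one mismatch.  Matching reads are
#' reoriented to the sense strand and trimmed of adaptor, barcode and
#' primer; the reverse-primer + adaptor-B tail is also removed when found at
#' the read end (at most 2 mismatches).  Non-matching reads are retained
#' with status `"unassigned"`.
#'
#' @param reads data frame of reads (`id`, `sequence`, `quality`).
#' @param cfg a [demux_config()].
#' @return data frame `id`, `group`, `orientation` (`"forward"` or
#'   `"reverse"`), `status` (`"assigned"`/`"unassigned"`), `sequence`,
#'   `quality` -- trimmed and sense-oriented for assigned reads, untouched
#'   for unassigned ones.
#' @export
demultiplex <- function(reads, cfg = demux_config()) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  n <- nrow(reads)
  if (n == 0L) {
    return(data.frame(id = character(0), group = character(0),
                      orientation = character(0), status = character(0),
                      sequence = character(0), quality = character(0),
                      stringsAsFactors = FALSE))
  }
  seqs <- toupper(reads$sequence)
  fwd <- .demux_one_strand(seqs, cfg)
  need_rc <- fwd$group == 0L
  group <- fwd$group
  orientation <- rep("forward", n)
  seq_out <- seqs
  qual_out <- reads$quality
  if (any(need_rc)) {
    rc <- revcomp(seqs[need_rc])
    bwd <- .demux_one_strand(rc, cfg)
    hit <- bwd$group > 0L
    idx <- which(need_rc)[hit]
    group[idx] <- bwd$group[hit]
    orientation[idx] <- "reverse"
    seq_out[idx] <- rc[hit]
    has_q <- !is.na(qual_out[idx])
    qual_out[idx][has_q] <- vapply(strsplit(qual_out[idx][has_q], ""),
                                   function(ch) paste(rev(ch), collapse = ""),
                                   character(1))
  }
  assigned <- group > 0L
  # trim prefix (adaptor+barcode+primer) and, when present, the reverse
  # primer + adaptor-B tail
  ins_start <- fwd$insert_start
  tail_pat <- paste0(revcomp(cfg$reverse_primer), revcomp(cfg$adaptor_b))
  lt <- nchar(tail_pat)
  if (any(assigned)) {
    s <- seq_out[assigned]
    q <- qual_out[assigned]
    len <- nchar(s)
    tail_at <- pmax(len - lt + 1L, 1L)
    tail_mm <- .mismatches_to(s, tail_pat, at = tail_at)
    end <- ifelse(tail_mm <= 2L & len - lt >= ins_start, len - lt, len)
    seq_out[assigned] <- substr(s, ins_start, end)
    qual_out[assigned] <- ifelse(is.na(q), q, substr(q, ins_start, end))
  }
  data.frame(id = reads$id,
             group = ifelse(assigned, names(cfg$barcodes)[pmax(group, 1L)],
                            NA_character_),
             orientation = ifelse(assigned, orientation, NA_character_),
             status = ifelse(assigned, "assigned", "unassigned"),
             sequence = ifelse(assigned, seq_out, seqs),
             quality = ifelse(assigned, qual_out, reads$quality),
             stringsAsFactors = FALSE)
}

#' Assign a single read
#'
#' Convenience wrapper around [demultiplex()] for one read.
#'
#' @param read one-row data frame, or a list with `id`, `sequence`,
#'   `quality`.
#' @param cfg a [demux_config()].
#' @return one-row data frame as in [demultiplex()].
#' @export
assign_group <- function(read, cfg = demux_config()) {
  df <- data.frame(id = read$id, sequence = read$sequence,
                   quality = if (is.null(read$quality)) NA_character_ else read$quality,
                   stringsAsFactors = FALSE)
  demultiplex(df, cfg)
}

#' Quality filter with average and end error-probability thresholds
#'
#' Reimplements the stated accept/reject criterion of Lucy-style amplicon
#' cleaning on already-trimmed reads: a read passes iff its mean per-base
#' error probability is at most `thr$max_avg_error` and every base within
#' `thr$end_window` bases of either end has error probability at most
#' `thr$max_end_error`.  No trimming is performed.
#'
#' @param reads data frame of reads with non-missing `quality` strings
#'   (Phred+33).
#' @param thr a [qc_thresholds()].
#' @return data frame `id`, `pass` (logical), `reason` (`NA`, `"average"`,
#'   or `"end"`; average takes precedence when both fail).
#' @export
lucy_filter <- function(reads, thr = qc_thresholds()) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  if (anyNA(reads$quality)) {
    stop("quality filter needs per-base qualities for every read", call. = FALSE)
  }
  phred <- .qual_to_phred(reads$quality)
  err <- lapply(phred, phred_to_error)
  avg_fail <- vapply(err, function(e) mean(e) > thr$max_avg_error, logical(1))
  w <- thr$end_window
  end_fail <- vapply(err, function(e) {
    k <- min(w, length(e))
    any(head(e, k) > thr$max_end_error) || any(tail(e, k) > thr$max_end_error)
  }, logical(1))
  data.frame(id = reads$id,
             pass = !(avg_fail | end_fail),
             reason = ifelse(avg_fail, "average",
                             ifelse(end_fail, "end", NA_character_)),
             stringsAsFactors = FALSE)
}
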