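# Readers and writers for every external format the pipeline touches:
# FASTQ/FASTA reads, chromatogram peak-height tables, qPCR Ct tables, and
# the isoform / site-frequency report TSVs.

.as_read_frame <- function(id, sequence, quality = NULL) {
  id <- unname(as.character(id))
  sequence <- unname(toupper(sequence))
  if (!is.null(quality)) quality <- unname(quality)
  .assert_dna(sequence, "read sequence")
  df <- data.frame(id = as.character(id), sequence = sequence,
                   stringsAsFactors = FALSE)
  if (!is.null(quality)) {
    if (any(nchar(quality) != nchar(sequence))) {
      bad <- which(nchar(quality) != nchar(sequence))[1]
      stop(sprintf("read %s: quality length %d != sequence length %d",
                   df$id[bad], nchar(quality)[bad], nchar(sequence)[bad]),
           call. = FALSE)
    }
    df$quality <- quality
  } else {
    df$quality <- rep(NA_character_, nrow(df))
  }
  df
}

#' Read a FASTQ file
#'
#' Phred+33 quality encoding is assumed.  Sequences are uppercased; read ids
#' are kept verbatim (text up to the first whitespace of the `@` header).
#'
#' @param path path to an (uncompressed or gzipped) FASTQ file.
#' @return data frame with character columns `id`, `sequence`, `quality`,
#'   one row per read, in file order.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  if (length(qs) == 0L) {
    return(.as_read_frame(character(0), character(0), character(0)))
  }
  seq_w <- Biostrings::width(qs)
  qual_w <- Biostrings::width(Biostrings::quality(qs))
  if (any(seq_w != qual_w)) {
    bad <- which(seq_w != qual_w)[1]
    stop(sprintf("malformed FASTQ record %d (%s): sequence length %d != quality length %d",
                 bad, names(qs)[bad], seq_w[bad], qual_w[bad]), call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(qs))
  .as_read_frame(ids, as.character(qs), as.character(Biostrings::quality(qs)))
}

#' Write reads to a FASTQ file
#'
#' @param reads data frame with columns `id`, `sequence`, `quality` (as
#'   returned by [read_fastq()] or [simulate_reads()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  if (anyNA(reads$quality)) stop("cannot write FASTQ: missing qualities", call. = FALSE)
  if (nrow(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$id
  qs <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    seqs, Biostrings::PhredQuality(reads$quality)))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path path to a FASTA file; wrapped sequence lines are concatenated.
#' @return data frame with columns `id`, `sequence` and an all-`NA`
#'   `quality` column.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  .as_read_frame(ids, as.character(ss))
}

#' Write reads to a FASTA file
#'
#' @inheritParams write_fastq
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a chromatogram peak-height table
#'
#' Expects delimited text (TSV or CSV, autodetected from the header line)
#' with columns `position`, `A`, `C`, `G`, `T` and optionally `call`.  When
#' the call column is absent the called base at each position is inferred as
#' the channel with the maximal height (ties broken in A, C, G, T order).
#'
#' @param path path to the table.
#' @return data frame of class `chromatogram_trace` with columns `position`,
#'   `A`, `C`, `G`, `T`, `call`.
#' @export
read_trace_table <- function(path) {
  stopifnot(file.exists(path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl(",", header, fixed = TRUE)) "," else "\t"
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  names(tab) <- sub("^call$", "call", tolower(names(tab)))
  names(tab)[names(tab) %in% c("a", "c", "g", "t")] <-
    toupper(names(tab)[names(tab) %in% c("a", "c", "g", "t")])
  chromatogram_trace(tab)
}

#' Construct / validate a chromatogram trace
#'
#' @param tab data frame with columns `position`, `A`, `C`, `G`, `T` and
#'   optionally `call`.
#' @return validated data frame of class `chromatogram_trace`.
#' @export
chromatogram_trace <- function(tab) {
  need <- c("position", "A", "C", "G", "T")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("trace table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  heights <- as.matrix(tab[, c("A", "C", "G", "T")])
  if (any(heights < 0)) stop("negative peak height in trace table", call. = FALSE)
  if (any(rowSums(heights) <= 0)) {
    stop("trace has positions with no signal in any channel", call. = FALSE)
  }
  if (!"call" %in% names(tab)) {
    tab$call <- c("A", "C", "G", "T")[max.col(heights, ties.method = "first")]
  }
  tab$call <- toupper(tab$call)
  out <- tab[, c("position", "A", "C", "G", "T", "call")]
  class(out) <- c("chromatogram_trace", "data.frame")
  out
}

#' Read a qPCR cycle-threshold table
#'
#' Expects a TSV with columns `sample_id`, `group`, `gene`, `ct`, `ref_ct`
#' where `ref_ct` is the matched endogenous-control (e.g. beta-actin) cycle
#' threshold.  Replicate rows per (sample, gene) are permitted and averaged
#' downstream.
#'
#' @param path path to the TSV.
#' @return data frame with the five columns above.
#' @export
read_qpcr_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gene", "ct", "ref_ct")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("qPCR table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(tab$ct)) || !all(is.finite(tab$ref_ct))) {
    stop("qPCR table contains non-finite Ct values", call. = FALSE)
  }
  tab[, need]
}

.fmt_pct <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))

#' Write an isoform count table
#'
#' TSV mirroring the isoform report layout: label, pattern, per-group counts
#' and relative occurrences (percentages of the combined grand total,
#' rendered to 2 decimals and always recomputed from the counts).
#'
#' @param table isoform count table from [tabulate_isoforms()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_isoform_table <- function(table, path) {
  out <- data.frame(
    label = table$label, pattern = table$pattern, protein = table$protein,
    count_lean = table$count_lean, pct_lean = .fmt_pct(table$pct_lean),
    count_obob = table$count_obob, pct_obob = .fmt_pct(table$pct_obob),
    count_total = table$count_total, pct_total = .fmt_pct(table$pct_total),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a written isoform count table
#'
#' @param path path to a TSV produced by [write_isoform_table()].
#' @return data frame with counts as integers and percentages as numerics.
#' @export
read_isoform_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  for (col in grep("^pct_", names(tab), value = TRUE)) {
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  tab
}

#' Write a site-frequency table
#'
#' TSV with one row per editing site: per-group edited/total counts, edited
#' percentages (2 decimals), the signed group difference, and Fisher
#' p-values when present.
#'
#' @param table site-frequency table from [site_frequencies()] or
#'   [compare_sites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(table, path) {
  out <- table
  for (col in c("pct_lean", "pct_obob", "delta_pct")) {
    if (col %in% names(out)) out[[col]] <- .fmt_pct(out[[col]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a written site-frequency table
#'
#' @param path path to a TSV produced by [write_site_table()].
#' @return data frame with numeric percentage columns.
#' @export
read_site_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  for (col in intersect(c("pct_lean", "pct_obob", "delta_pct"), names(tab))) {
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  tab
}
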