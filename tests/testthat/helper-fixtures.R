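# Shared fixtures built in code.

ref <- edcas::default_reference()

# Unedited-or-edited cassette sequence for an edited-site string.
cassette_seq <- function(sites, reference = ref) {
  s <- reference$sequence
  if (nzchar(sites)) {
    for (x in strsplit(sites, "")[[1]]) {
      pos <- reference$site_offsets[[x]]
      substr(s, pos, pos) <- "G"
    }
  }
  s
}

# A trimmed, sense-oriented read carrying the cassette with the given code.
trimmed_read <- function(sites, id = "r1", group = "lean", reference = ref) {
  data.frame(id = id,
             sequence = paste0(reference$amplicon_flank5, cassette_seq(sites, reference),
                               reference$amplicon_flank3),
             group = group, stringsAsFactors = FALSE)
}

# Reads data frame from parallel vectors of ids/sequences (+ uniform quality).
reads_frame <- function(sequence, id = sprintf("r%03d", seq_along(sequence)),
                        phred = 40L) {
  data.frame(id = id, sequence = sequence,
             quality = vapply(nchar(sequence),
                              function(n) strrep(intToUtf8(phred + 33L), n),
                              character(1)),
             stringsAsFactors = FALSE)
}

# Site-call rows constructed directly (bypassing alignment) for aggregation
# tests: one row per read, `sites` = edited-site string.
calls_frame <- function(sites, group) {
  out <- data.frame(read_id = sprintf("r%06d", seq_along(sites)),
                    group = group, stringsAsFactors = FALSE)
  for (s in c("A", "B", "E", "C", "D")) {
    out[[s]] <- ifelse(grepl(s, sites), "edited", "unedited")
  }
  out$status <- rep("classified", nrow(out))
  out$reason <- rep(NA_character_, nrow(out))
  out
}

# Exhaustive oracle for the two-sided Fisher test: enumerate every 2x2
# table with the observed margins, compute each probability from binomial
# coefficients, and sum those not exceeding the observed table's.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, tab[1, 1]) * choose(n, k - tab[1, 1]) / choose(m + n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Expand the packaged per-isoform counts into per-read call rows.
calls_from_counts <- function(counts = edcas::hypothalamus_isoform_counts()) {
  sites <- ifelse(counts$edited_sites == "-", "", counts$edited_sites)
  rbind(calls_frame(rep(sites, counts$count_lean), "lean"),
        calls_frame(rep(sites, counts$count_obob), "obob"))
}
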