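# Synthetic-data generators: barcoded amplicon reads with configurable
# editing structure, chromatogram traces with known editing mixtures, and
# qPCR Ct records with known fold changes.  Every generator is
# deterministic under a fixed seed.

# Build the sense-strand amplicon for one editing code.
.amplicon_for_code <- function(sites, group, cfg, ref) {
  cass <- ref$sequence
  if (nzchar(sites)) {
    for (s in strsplit(sites, "")[[1]]) {
      pos <- ref$site_offsets[[s]]
      substr(cass, pos, pos) <- "G"
    }
  }
  paste0(cfg$adaptor_a, cfg$barcodes[[group]], cfg$forward_primer,
         ref$amplicon_flank5, cass, ref$amplicon_flank3,
         revcomp(cfg$reverse_primer), revcomp(cfg$adaptor_b))
}

# Draw editing codes from per-site probabilities, optionally correlated
# through an exchangeable Gaussian copula (linkage in [0, 1); 0 =
# independent sites).
.draw_codes <- function(n, probs, linkage = 0) {
  stopifnot(identical(sort(names(probs)), sort(EDIT_SITES)),
            all(probs >= 0), all(probs <= 1), linkage >= 0, linkage < 1)
  probs <- probs[EDIT_SITES]
  if (linkage > 0) {
    z0 <- rnorm(n)
    z <- sqrt(linkage) * z0 + sqrt(1 - linkage) * matrix(rnorm(n * 5L), n, 5L)
    edited <- sweep(z, 2L, qnorm(probs), "<")
  } else {
    edited <- matrix(runif(n * 5L), n, 5L) < rep(probs, each = n)
  }
  apply(edited, 1L, function(r) paste(EDIT_SITES[r], collapse = ""))
}

# Inject iid substitution errors at rate eps; the substitute base is drawn
# uniformly from the three alternatives.
.inject_substitutions <- function(seqs, eps) {
  if (eps <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < eps)
    if (length(hit) == 0L) return(s)
    ch <- strsplit(s, "")[[1]]
    for (i in hit) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.inject_indels <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (length(hit) == 0L) return(s)
    ch <- strsplit(s, "")[[1]]
    for (i in rev(hit)) {
      if (runif(1) < 0.5) {
        ch <- append(ch, sample(bases, 1L), after = i)
      } else {
        ch <- ch[-i]
      }
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.quality_strings <- function(lens, mean, sd) {
  vapply(lens, function(n) {
    q <- as.integer(round(rnorm(n, mean, sd)))
    q[q < 2L] <- 2L
    q[q > 41L] <- 41L
    intToUtf8(q + 33L)
  }, character(1))
}

#' Simulate barcoded editing-cassette amplicon reads
#'
#' Generates full-length sense amplicons
#' `adaptor A + group barcode + forward primer + 5' flank + cassette +
#' 3' flank + rc(reverse primer) + rc(adaptor B)` (~300 bp with the
#' built-in reference), one per simulated read, then optionally
#' reverse-complements each read with probability 0.5, injects iid
#' substitution (and optional indel) errors, and attaches Gaussian
#' Phred qualities.
#'
#' The editing structure comes from exactly one of two modes:
#' * `counts` -- a data frame `edited_sites`, `count_lean`, `count_obob`
#'   (or `count_<group>` for other group names): exactly that many reads of
#'   each code per group are emitted;
#' * `site_probs` -- a named list, one element per group, each a named
#'   probability vector over sites `A, B, E, C, D`; each read's code is
#'   drawn by independent (or copula-linked, see `linkage`) Bernoulli site
#'   draws, with `n_per_group` reads per group.
#'
#' @param counts per-code per-group counts data frame (counts mode).
#' @param site_probs per-group named site-probability vectors (probability
#'   mode).
#' @param n_per_group reads per group (probability mode); recycled over
#'   groups or named per group.
#' @param linkage exchangeable between-site correlation of the latent
#'   editing draws, in `[0, 1)` (probability mode; default 0 = independent).
#' @param base_error_rate per-base substitution error probability.
#' @param indel_rate per-base insertion/deletion probability (default 0).
#' @param quality_mean,quality_sd Gaussian Phred-score distribution
#'   (clamped to 2..41).
#' @param random_orientation reverse-complement each read with probability
#'   0.5 (default `FALSE` = all forward).
#' @param seed integer seed; when non-`NULL` the output is reproducible and
#'   the caller's RNG state is left untouched.
#' @param demux a [demux_config()] supplying adaptors, barcodes, primers.
#' @param ref a [cassette_reference()] with amplicon flanks.
#' @return data frame of reads (`id`, `sequence`, `quality`) plus a
#'   `truth_group` and `truth_sites` column recording the generating truth.
#' @export
simulate_reads <- function(counts = NULL, site_probs = NULL,
                           n_per_group = 1000L, linkage = 0,
                           base_error_rate = 0, indel_rate = 0,
                           quality_mean = 35, quality_sd = 3,
                           random_orientation = FALSE, seed = NULL,
                           demux = demux_config(), ref = default_reference()) {
  if (is.null(counts) == is.null(site_probs)) {
    stop("give exactly one of `counts` or `site_probs`", call. = FALSE)
  }
  run <- function() {
    if (!is.null(counts)) {
      groups <- sub("^count_", "", grep("^count_", names(counts), value = TRUE))
      per_group <- lapply(groups, function(g) {
        k <- counts[[paste0("count_", g)]]
        sites <- counts$edited_sites
        sites[is.na(sites) | sites == "-"] <- ""
        rep(sites, k)
      })
      names(per_group) <- groups
    } else {
      groups <- names(site_probs)
      if (is.null(groups)) stop("site_probs must be a named list", call. = FALSE)
      npg <- if (is.null(names(n_per_group))) {
        setNames(rep_len(n_per_group, length(groups)), groups)
      } else n_per_group
      per_group <- lapply(groups, function(g) {
        .draw_codes(npg[[g]], site_probs[[g]], linkage)
      })
      names(per_group) <- groups
    }
    truth_group <- rep(names(per_group), lengths(per_group))
    truth_sites <- unlist(per_group, use.names = FALSE)
    n <- length(truth_sites)
    if (n == 0L) {
      out <- .as_read_frame(character(0), character(0), character(0))
      out$truth_group <- character(0)
      out$truth_sites <- character(0)
      return(out)
    }
    # one amplicon per distinct (group, code), then index
    key <- paste(truth_group, truth_sites, sep = "|")
    uk <- unique(key)
    amp_map <- setNames(vapply(uk, function(k) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1]]
      .amplicon_for_code(if (length(parts) > 1L) parts[2] else "", parts[1],
                         demux, ref)
    }, character(1)), uk)
    seqs <- unname(amp_map[key])
    seqs <- .inject_substitutions(seqs, base_error_rate)
    seqs <- .inject_indels(seqs, indel_rate)
    if (random_orientation) {
      flip <- runif(n) < 0.5
      if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
    }
    qual <- .quality_strings(nchar(seqs), quality_mean, quality_sd)
    out <- .as_read_frame(sprintf("read_%06d", seq_len(n)), seqs, qual)
    out$truth_group <- truth_group
    out$truth_sites <- truth_sites
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a chromatogram trace over the cassette reference
#'
#' Builds a per-position four-channel peak-height table for the reference
#' sequence: the template-base channel carries `peak_scale * (1 - m)` and,
#' at an editing site with mixture `m > 0`, the G channel carries
#' `peak_scale * m` (the edited-template fraction); Gaussian noise of
#' standard deviation `noise_sd` is added to every channel and heights are
#' clamped at zero.  `orientation = "reverse_complement"` emits the
#' reverse-complemented trace (reversed positions, A/T and C/G channels
#' swapped).
#'
#' @param mixture named numeric vector of edited-template fractions per
#'   site (missing sites default to 0).
#' @param peak_scale height of a pure single-template peak.
#' @param noise_sd Gaussian height noise (default 0).
#' @param orientation `"forward"` or `"reverse_complement"`.
#' @param seed integer seed (see [simulate_reads()]).
#' @param ref a [cassette_reference()].
#' @return a [chromatogram_trace()].
#' @export
simulate_trace <- function(mixture = c(A = 0), peak_scale = 1000,
                           noise_sd = 0,
                           orientation = c("forward", "reverse_complement"),
                           seed = NULL, ref = default_reference()) {
  orientation <- match.arg(orientation)
  stopifnot(all(mixture >= 0), all(mixture <= 1),
            all(names(mixture) %in% EDIT_SITES))
  run <- function() {
    n <- nchar(ref$sequence)
    bases <- strsplit(ref$sequence, "")[[1]]
    h <- matrix(0, nrow = n, ncol = 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
    m <- setNames(rep(0, 5L), EDIT_SITES)
    m[names(mixture)] <- mixture
    for (i in seq_len(n)) h[i, bases[i]] <- peak_scale
    for (s in EDIT_SITES) {
      pos <- ref$site_offsets[[s]]
      h[pos, "A"] <- peak_scale * (1 - m[[s]])
      h[pos, "G"] <- h[pos, "G"] + peak_scale * m[[s]]
    }
    if (noise_sd > 0) {
      h <- h + matrix(rnorm(length(h), 0, noise_sd), nrow = n)
      h[h < 0] <- 0
    }
    calls <- colnames(h)[max.col(h, ties.method = "first")]
    tr <- chromatogram_trace(data.frame(position = seq_len(n),
                                        A = h[, "A"], C = h[, "C"],
                                        G = h[, "G"], T = h[, "T"],
                                        call = calls, stringsAsFactors = FALSE))
    if (orientation == "reverse_complement") tr <- .revcomp_trace(tr)
    tr
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate qPCR Ct records with known group effects
#'
#' Each simulated animal's true delta-Ct (target Ct minus endogenous-control
#' Ct) is the group/gene mean plus Gaussian biological noise; the record is
#' emitted as technical triplicates around a fixed reference Ct.  A group
#' delta-Ct lower by 1 cycle corresponds to a 2-fold higher relative
#' expression under the 2^-deltaCt transform.
#'
#' @param delta_ct data frame `group`, `gene`, `delta_ct` of true mean
#'   delta-Ct values, or a named numeric vector (names = groups) for a
#'   single gene (`gene = "target"`).
#' @param sigma between-animal Gaussian SD of delta-Ct, in cycles.
#' @param n_per_group animals per group.
#' @param n_replicates technical replicates per animal (default 3).
#' @param rep_sd within-triplicate technical SD in cycles (default 0.05).
#' @param ref_ct fixed endogenous-control Ct (default 18).
#' @param seed integer seed (see [simulate_reads()]).
#' @return data frame `sample_id`, `group`, `gene`, `ct`, `ref_ct` suitable
#'   for [qpcr_fold_change()].
#' @export
simulate_qpcr <- function(delta_ct, sigma = 0.2, n_per_group = 8L,
                          n_replicates = 3L, rep_sd = 0.05, ref_ct = 18,
                          seed = NULL) {
  if (!is.data.frame(delta_ct)) {
    delta_ct <- data.frame(group = names(delta_ct), gene = "target",
                           delta_ct = unname(delta_ct),
                           stringsAsFactors = FALSE)
  }
  stopifnot(sigma >= 0, n_per_group >= 0)
  run <- function() {
    rows <- list()
    for (i in seq_len(nrow(delta_ct))) {
      g <- delta_ct$group[i]
      gene <- delta_ct$gene[i]
      for (a in seq_len(n_per_group)) {
        true_dct <- delta_ct$delta_ct[i] + rnorm(1L, 0, sigma)
        ct <- ref_ct + true_dct + rnorm(n_replicates, 0, rep_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%02d", g, a), group = g, gene = gene,
          ct = ct, ref_ct = ref_ct, stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L) {
      return(data.frame(sample_id = character(0), group = character(0),
                        gene = character(0), ct = numeric(0),
                        ref_ct = numeric(0), stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
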