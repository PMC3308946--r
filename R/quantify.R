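# Aggregation of site calls into the isoform count table and the per-site
# frequency table, group comparison by Fisher's exact test with Bonferroni
# correction, and 2^-deltaCt qPCR fold changes.

#' Tabulate classified calls into the 32-row isoform count table
#'
#' Counts classified reads per (group, editing code).  All 32 codes are
#' retained even at count zero.  The three relative-occurrence columns all
#' use the combined grand total across both groups as denominator.
#'
#' @param calls data frame from [call_sites()] (classified rows are used;
#'   rejected rows are refused unless `strict = FALSE`).
#' @param groups character vector of the two group labels, control first
#'   (columns are named `count_<group>`; defaults `c("lean", "obob")`).
#' @param order row order: `"canonical"` (code enumeration order) or
#'   `"frequency"` (decreasing total count, the conventional report order).
#' @param strict refuse non-classified rows (default `TRUE`).
#' @return data frame with columns `sites`, `label`, `pattern`, `protein`,
#'   `count_lean`, `count_obob`, `count_total`, `pct_lean`, `pct_obob`,
#'   `pct_total`.  Percentages are `NA` when the grand total is zero.
#' @export
tabulate_isoforms <- function(calls, groups = c("lean", "obob"),
                              order = c("canonical", "frequency"),
                              strict = TRUE) {
  order <- match.arg(order)
  stopifnot(length(groups) == 2L)
  if (strict && any(calls$status != "classified")) {
    stop("tabulate_isoforms() expects classified calls only", call. = FALSE)
  }
  calls <- calls[calls$status == "classified", , drop = FALSE]
  if (nrow(calls) > 0L && !all(calls$group %in% groups)) {
    bad <- setdiff(unique(calls$group), groups)
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  codes <- enumerate_codes()
  tab <- data.frame(sites = codes$sites,
                    label = isoform_label(codes$sites),
                    pattern = pattern_for_code(codes$sites),
                    protein = translate_code(codes$sites),
                    stringsAsFactors = FALSE)
  code_str <- if (nrow(calls) > 0L) code_of(calls) else character(0)
  for (i in 1:2) {
    cnt <- table(factor(code_str[calls$group == groups[i]], levels = codes$sites))
    tab[[paste0("count_", groups[i])]] <- as.integer(cnt)
  }
  c1 <- tab[[paste0("count_", groups[1])]]
  c2 <- tab[[paste0("count_", groups[2])]]
  tab$count_total <- c1 + c2
  grand <- sum(tab$count_total)
  pct <- function(x) if (grand > 0L) 100 * x / grand else rep(NA_real_, length(x))
  tab[[paste0("pct_", groups[1])]] <- pct(c1)
  tab[[paste0("pct_", groups[2])]] <- pct(c2)
  tab$pct_total <- pct(tab$count_total)
  if (order == "frequency") {
    tab <- tab[order(-tab$count_total, tab$sites), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Per-site editing frequencies by group
#'
#' For each of the five sites, the fraction of tallied reads carrying the
#' edited base, per group, and the signed group difference
#' `delta_pct = pct_<case> - pct_<control>` (case group minus control, so a
#' positive delta means more editing in the case group).
#'
#' Two tallies are available.  The default `tally = "read"` uses only fully
#' classified reads, so every site shares one denominator per group.
#' `tally = "site"` tallies each site over all reads whose call at that site
#' is unambiguous, giving per-site denominators (slightly larger when reads
#' are ambiguous at other sites only).
#'
#' @param calls data frame from [call_sites()].
#' @param groups the two group labels, control first (default
#'   `c("lean", "obob")`).
#' @param tally `"read"` (read-level exclusion of ambiguity) or `"site"`
#'   (per-site exclusion).
#' @return data frame with one row per site: `site`, `edited_lean`,
#'   `total_lean`, `edited_obob`, `total_obob`, `pct_lean`, `pct_obob`,
#'   `delta_pct`.  Percentages are `NA` (not silently 0) for empty
#'   denominators.
#' @export
site_frequencies <- function(calls, groups = c("lean", "obob"),
                             tally = c("read", "site")) {
  tally <- match.arg(tally)
  stopifnot(length(groups) == 2L)
  out <- data.frame(site = EDIT_SITES, stringsAsFactors = FALSE)
  for (g in groups) {
    sub <- calls[!is.na(calls$group) & calls$group == g, , drop = FALSE]
    if (tally == "read") sub <- sub[sub$status == "classified", , drop = FALSE]
    edited <- integer(5L)
    total <- integer(5L)
    for (k in seq_along(EDIT_SITES)) {
      v <- sub[[EDIT_SITES[k]]]
      if (tally == "site") v <- v[v != "ambiguous"]
      edited[k] <- sum(v == "edited")
      total[k] <- length(v)
    }
    out[[paste0("edited_", g)]] <- edited
    out[[paste0("total_", g)]] <- total
    out[[paste0("pct_", g)]] <- ifelse(total > 0L, 100 * edited / total, NA_real_)
  }
  out$delta_pct <- out[[paste0("pct_", groups[2])]] - out[[paste0("pct_", groups[1])]]
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the probability-mass rule: with margins
#' fixed, all tables whose hypergeometric probability does not exceed that
#' of the observed table (within a relative tolerance of 1e-7) contribute
#' to p.  Probabilities are accumulated in log space, so totals of order
#' 10^4 and beyond are handled without underflow.  The odds ratio is the
#' sample odds ratio, with a Haldane correction of 0.5 added to every cell
#' when any cell is zero.
#'
#' @param table 2x2 matrix (or 4-vector, column-major) of non-negative
#'   integer counts; rows = outcome (e.g. edited/unedited), columns = group.
#' @return object of class `fisher_result`: list with `table`,
#'   `p_two_sided`, `odds_ratio`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_two_sided   # 1
fisher_exact_2x2 <- function(table) {
  tab <- matrix(as.numeric(table), 2L, 2L)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers", call. = FALSE)
  }
  m <- sum(tab[1, ])   # row-1 margin
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])   # column-1 margin
  or <- if (any(tab == 0)) {
    ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) / ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  } else {
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
  if (m + n == 0 || k == 0 || k == m + n || m == 0 || n == 0) {
    warning("degenerate margin: p-value is 1 by convention")
    p <- 1
  } else {
    support <- max(0, k - n):min(k, m)
    logp <- dhyper(support, m, n, k, log = TRUE)
    obs <- dhyper(tab[1, 1], m, n, k, log = TRUE)
    p <- min(1, sum(exp(logp[logp <= obs + 1e-7])))
  }
  structure(list(table = matrix(as.integer(tab), 2L, 2L),
                 p_two_sided = p, odds_ratio = or),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Fisher's exact test (two-sided, probability-mass rule)\n")
  print(x$table)
  cat(sprintf("p = %.4g, odds ratio = %.4g\n", x$p_two_sided, x$odds_ratio))
  invisible(x)
}

#' Compare per-site editing between groups
#'
#' Runs [fisher_exact_2x2()] per site on
#' `[[edited_ctrl, unedited_ctrl], [edited_case, unedited_case]]` and
#' applies a Bonferroni correction over the five sites
#' (`p_adjusted = min(1, 5 p)`).
#'
#' @param freq site-frequency table from [site_frequencies()].
#' @param groups the two group labels, control first.
#' @return `freq` with columns `p_value`, `p_adjusted` appended.
#' @export
compare_sites <- function(freq, groups = c("lean", "obob")) {
  e1 <- freq[[paste0("edited_", groups[1])]]
  t1 <- freq[[paste0("total_", groups[1])]]
  e2 <- freq[[paste0("edited_", groups[2])]]
  t2 <- freq[[paste0("total_", groups[2])]]
  p <- vapply(seq_len(nrow(freq)), function(i) {
    if (t1[i] == 0L || t2[i] == 0L) return(NA_real_)
    fisher_exact_2x2(matrix(c(e1[i], t1[i] - e1[i], e2[i], t2[i] - e2[i]), 2L))$p_two_sided
  }, numeric(1))
  freq$p_value <- p
  freq$p_adjusted <- pmin(1, nrow(freq) * p)
  freq
}

#' qPCR relative expression and fold change by the 2^-deltaCt method
#'
#' Technical replicates are first averaged per (sample, gene); each
#' sample's relative expression is `2^-(ct - ref_ct)` against its
#' endogenous-control Ct.  Per (group, gene) the mean and SEM of relative
#' expression are reported; the fold change is the group mean divided by the
#' control-group mean of the same gene.  Groups are compared per gene with
#' Welch's two-tailed unpaired t-test on the per-sample relative
#' expressions, Bonferroni-corrected across the genes tested.
#'
#' @param records data frame with columns `sample_id`, `group`, `gene`,
#'   `ct`, `ref_ct` (see [read_qpcr_table()]).
#' @param control control group label (default `"lean"`).
#' @return data frame with one row per (group, gene): `group`, `gene`, `n`,
#'   `mean_rel`, `sem_rel`, `fold_change`, and (on non-control rows)
#'   `p_value`, `p_adjusted`.
#' @export
#' @examples
#' rec <- data.frame(sample_id = c("s1", "s2"), group = c("lean", "obob"),
#'                   gene = "Htr2c", ct = c(25, 24), ref_ct = c(20, 20))
#' qpcr_fold_change(rec)
qpcr_fold_change <- function(records, control = "lean") {
  need <- c("sample_id", "group", "gene", "ct", "ref_ct")
  stopifnot(all(need %in% names(records)))
  if (anyNA(records$ref_ct)) stop("missing reference-gene Ct", call. = FALSE)
  if (!control %in% records$group) {
    stop("control group '", control, "' absent from records", call. = FALSE)
  }
  # average technical replicates per sample
  per_sample <- aggregate(cbind(ct, ref_ct) ~ sample_id + group + gene,
                          data = records, FUN = mean)
  per_sample$rel <- 2^(-(per_sample$ct - per_sample$ref_ct))
  genes <- unique(per_sample$gene)
  groups <- unique(per_sample$group)
  groups <- c(control, setdiff(groups, control))
  rows <- list()
  for (gene in genes) {
    gsub_ <- per_sample[per_sample$gene == gene, , drop = FALSE]
    ctrl_rel <- gsub_$rel[gsub_$group == control]
    for (g in groups) {
      rel <- gsub_$rel[gsub_$group == g]
      if (length(rel) == 0L) next
      p <- NA_real_
      if (g != control && length(rel) > 1L && length(ctrl_rel) > 1L) {
        # constant data (e.g. noise-free simulations) leaves Welch's test
        # undefined; report NA rather than fail
        p <- tryCatch(t.test(rel, ctrl_rel, var.equal = FALSE)$p.value,
                      error = function(e) NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, gene = gene, n = length(rel),
        mean_rel = mean(rel),
        sem_rel = if (length(rel) > 1L) stats::sd(rel) / sqrt(length(rel)) else NA_real_,
        fold_change = mean(rel) / mean(ctrl_rel),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_value * length(genes))
  rownames(out) <- NULL
  out
}

#' Reference hypothalamic isoform counts
#'
#' Packaged per-group pyrosequencing read counts for each of the 32
#' isoforms from the reference hypothalamus dataset (lean control vs
#' leptin-deficient ob/ob mice), used as a simulation configuration and as
#' a fixture for the aggregation code.
#'
#' @return data frame with columns `edited_sites`, `count_lean`,
#'   `count_obob`.
#' @export
hypothalamus_isoform_counts <- function() {
  path <- system.file("extdata", "hypothalamus_isoform_counts.tsv",
                      package = "edcas", mustWork = TRUE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$edited_sites[is.na(tab$edited_sites) | tab$edited_sites == "-"] <- ""
  tab
}

#' Reference hypothalamic per-site editing percentages
#'
#' Packaged per-site editing percentages (lean control vs ob/ob) from the
#' reference hypothalamus dataset.
#'
#' @return data frame with columns `site`, `pct_lean`, `pct_obob`.
#' @export
hypothalamus_site_editing <- function() {
  path <- system.file("extdata", "hypothalamus_site_editing.tsv",
                      package = "edcas", mustWork = TRUE)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
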