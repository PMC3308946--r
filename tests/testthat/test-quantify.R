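test_that("isoform tabulation reproduces the reference count table", {
  counts <- hypothalamus_isoform_counts()
  calls <- calls_from_counts(counts)
  tab <- tabulate_isoforms(calls)
  expect_equal(sum(tab$count_total), nrow(calls))       # conservation
  key <- ifelse(counts$edited_sites == "-", "", counts$edited_sites)
  expect_equal(tab$count_lean[match(key, tab$sites)], counts$count_lean)
  expect_equal(tab$count_obob[match(key, tab$sites)], counts$count_obob)
  # combined relative occurrences, 2-decimal rendering
  expect_equal(round(tab$pct_total[tab$sites == "ABD"], 2), 33.58)
  expect_equal(round(tab$pct_total[tab$sites == "AB"], 2), 19.31)
  expect_equal(round(tab$pct_total[tab$sites == "ABCD"], 2), 11.32)
  expect_equal(round(tab$pct_total[tab$sites == ""], 2), 6.24)
  expect_equal(round(tab$pct_obob[tab$sites == "AB"], 2), 10.38)
  expect_equal(round(tab$pct_obob[tab$sites == ""], 2), 2.81)
  # zero rows are retained
  expect_equal(sum(tab$count_total == 0), 5L)

  single <- tabulate_isoforms(calls_frame("", "lean"))
  expect_equal(single$count_lean[single$sites == ""], 1L)
  expect_equal(single$pct_total[single$sites == ""], 100)
  expect_error(tabulate_isoforms(calls_frame("", "mystery")), "unknown group")
})

test_that("site frequencies match a brute-force tally over the counts", {
  counts <- hypothalamus_isoform_counts()
  calls <- calls_from_counts(counts)
  freq <- site_frequencies(calls)
  # independent tally: sum counts of isoforms containing each site letter
  for (s in c("A", "B", "E", "C", "D")) {
    lean <- sum(counts$count_lean[grepl(s, counts$edited_sites)])
    expect_equal(freq$edited_lean[freq$site == s], lean)
  }
  expect_equal(freq$pct_lean[freq$site == "A"], 87.55438, tolerance = 1e-6)
  expect_equal(freq$pct_lean[freq$site == "D"], 55.25818, tolerance = 1e-6)

  expect_equal(site_frequencies(calls_frame(rep("", 5), "lean"))$pct_lean,
               rep(0, 5))
  expect_equal(site_frequencies(calls_frame(rep("ABECD", 5), "obob"))$pct_obob,
               rep(100, 5))
  # empty denominators flagged as NA, not silently zero
  expect_true(all(is.na(site_frequencies(calls_frame(character(0), character(0)))$pct_lean)))
})

test_that("per-site tally uses all unambiguous calls at that site", {
  calls <- calls_frame(c("A", "A", ""), "lean")
  calls$E[1] <- "ambiguous"
  calls$status[1] <- "rejected"
  read_level <- site_frequencies(calls)
  per_site <- site_frequencies(calls, tally = "site")
  expect_equal(read_level$total_lean, rep(2L, 5))
  expect_equal(per_site$total_lean, c(3L, 3L, 2L, 3L, 3L))
  expect_equal(per_site$edited_lean[per_site$site == "A"], 2L)
})

test_that("fisher test matches closed forms and the exhaustive oracle", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_two_sided, 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))$p_two_sided,
               2 / choose(20, 10))
  set.seed(11)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    cc <- sample(0:(n - a - b), 1); d <- n - a - b - cc
    tab <- matrix(c(a, b, cc, d), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_two_sided, oracle_fisher_p(tab),
                 tolerance = 1e-12)
  }
  # large-margin stability: agrees with the normal-approximation z-test
  # within an order of magnitude at totals ~10^4
  big <- matrix(c(9258, 10574 - 9258, 9348, 10377 - 9348), 2)
  p_fisher <- fisher_exact_2x2(big)$p_two_sided
  p_z <- prop.test(c(9258, 9348), c(10574, 10377), correct = FALSE)$p.value
  expect_true(abs(log10(p_fisher) - log10(p_z)) < 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_warning(p0 <- fisher_exact_2x2(matrix(c(0, 3, 0, 4), 2))$p_two_sided,
                 "degenerate")
  expect_equal(p0, 1)
})

test_that("fisher result is invariant under simultaneous row/column swaps", {
  set.seed(3)
  for (i in 1:20) {
    tab <- matrix(sample(0:40, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    swapped <- tab[2:1, 2:1]
    expect_equal(fisher_exact_2x2(tab)$p_two_sided,
                 fisher_exact_2x2(swapped)$p_two_sided, tolerance = 1e-12)
  }
})

test_that("site comparison applies Bonferroni and is label-antisymmetric", {
  counts <- hypothalamus_isoform_counts()
  calls <- calls_from_counts(counts)
  cmp <- compare_sites(site_frequencies(calls))
  expect_equal(cmp$p_adjusted, pmin(1, 5 * cmp$p_value))
  # same proportions in both groups -> p = 1 (the four never-edited sites
  # have an empty margin and warn)
  flat <- suppressWarnings(compare_sites(site_frequencies(
    rbind(calls_frame(c("A", ""), "lean"), calls_frame(c("A", ""), "obob")))))
  expect_equal(flat$p_value[flat$site == "A"], 1)
  expect_equal(flat$p_adjusted[flat$site == "A"], 1)
  # swapping group labels negates delta and leaves p unchanged
  swapped_calls <- calls
  swapped_calls$group <- ifelse(calls$group == "lean", "obob", "lean")
  cmp2 <- compare_sites(site_frequencies(swapped_calls))
  expect_equal(cmp2$delta_pct, -cmp$delta_pct)
  expect_equal(cmp2$p_value, cmp$p_value, tolerance = 1e-12)
})

test_that("qPCR fold change implements 2^-deltaCt with replicate averaging", {
  rec <- data.frame(sample_id = rep(c("l1", "l2", "o1", "o2"), each = 1),
                    group = c("lean", "lean", "obob", "obob"),
                    gene = "g",
                    ct = c(20, 20, 19, 19), ref_ct = 20)
  out <- qpcr_fold_change(rec)
  expect_equal(out$mean_rel[out$group == "lean"], 1)     # ct = ref_ct
  expect_equal(out$fold_change[out$group == "obob"], 2)  # deltaCt -1
  # deltaCt = 1 -> relative expression 0.5
  rec2 <- data.frame(sample_id = c("l1", "o1"), group = c("lean", "obob"),
                     gene = "g", ct = c(20, 21), ref_ct = 20)
  out2 <- qpcr_fold_change(rec2)
  expect_equal(out2$mean_rel[out2$group == "obob"], 0.5)
  # technical replicates are averaged per sample before transformation
  rec3 <- data.frame(sample_id = "l1", group = "lean", gene = "g",
                     ct = c(19, 20, 21), ref_ct = 20)
  expect_equal(qpcr_fold_change(rec3)$mean_rel, 1)
  expect_equal(qpcr_fold_change(rec3)$n, 1L)
  expect_error(qpcr_fold_change(data.frame(sample_id = "s", group = "obob",
                                           gene = "g", ct = 1, ref_ct = 2)),
               "control group")
})
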