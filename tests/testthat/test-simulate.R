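test_that("read simulation is deterministic under a fixed seed", {
  cnt <- data.frame(edited_sites = c("", "ABD"), count_lean = c(3, 2),
                    count_obob = c(1, 4))
  r1 <- simulate_reads(counts = cnt, base_error_rate = 0.01,
                       random_orientation = TRUE, seed = 123)
  r2 <- simulate_reads(counts = cnt, base_error_rate = 0.01,
                       random_orientation = TRUE, seed = 123)
  expect_identical(r1, r2)
  r3 <- simulate_reads(counts = cnt, base_error_rate = 0.01,
                       random_orientation = TRUE, seed = 124)
  expect_false(identical(r1$sequence, r3$sequence))
  expect_identical(simulate_qpcr(c(lean = 5, obob = 4), seed = 9),
                   simulate_qpcr(c(lean = 5, obob = 4), seed = 9))
})

test_that("zero-error reads round-trip losslessly through the pipeline", {
  set.seed(31)
  codes <- enumerate_codes()$sites
  for (rep_i in 1:3) {
    picked <- sample(codes, 6)
    cnt <- data.frame(edited_sites = picked,
                      count_lean = sample(0:20, 6, replace = TRUE),
                      count_obob = sample(0:20, 6, replace = TRUE))
    reads <- simulate_reads(counts = cnt, seed = 1000 + rep_i,
                            random_orientation = (rep_i == 3))
    res <- run_pipeline(reads)
    expect_equal(res$manifest$counts$classified, sum(cnt$count_lean) + sum(cnt$count_obob))
    tab <- res$isoforms
    expect_equal(tab$count_lean[match(picked, tab$sites)], cnt$count_lean)
    expect_equal(tab$count_obob[match(picked, tab$sites)], cnt$count_obob)
  }
})

test_that("site-probability mode recovers its generating frequencies", {
  probs <- list(lean = c(A = 0.87, B = 0.75, E = 0.04, C = 0.24, D = 0.55))
  n <- 2000L
  reads <- simulate_reads(site_probs = probs, n_per_group = n, seed = 77)
  res <- run_pipeline(reads)
  freq <- site_frequencies(res$calls)
  p_hat <- freq$pct_lean / 100
  se <- sqrt(probs$lean * (1 - probs$lean) / n)
  expect_true(all(abs(p_hat - probs$lean) <= 3 * se))
})

test_that("linked site draws keep their marginal probabilities", {
  probs <- c(A = 0.6, B = 0.3, E = 0.1, C = 0.5, D = 0.8)
  withr::with_seed(4, {
    codes <- edcas:::.draw_codes(4000L, probs, linkage = 0.5)
  })
  for (s in names(probs)) {
    p_hat <- mean(grepl(s, codes))
    se <- sqrt(probs[[s]] * (1 - probs[[s]]) / 4000)
    expect_lt(abs(p_hat - probs[[s]]), 4 * se)
  }
  # positive linkage raises the joint A&B frequency above independence
  withr::with_seed(4, {
    ind <- edcas:::.draw_codes(4000L, probs, linkage = 0)
  })
  joint_linked <- mean(grepl("A", codes) & grepl("B", codes))
  joint_ind <- mean(grepl("A", ind) & grepl("B", ind))
  expect_gt(joint_linked, joint_ind)
})

test_that("substitution errors produce the expected rejection rate", {
  eps <- 0.01
  n <- 3000L
  reads <- simulate_reads(site_probs = list(lean = c(A = 0.5, B = 0.5, E = 0.1,
                                                     C = 0.3, D = 0.5)),
                          n_per_group = n, base_error_rate = eps, seed = 55)
  res <- run_pipeline(reads)
  # a site call becomes ambiguous when an error turns the base into C or T
  # (2/3 of substitutions); with 5 sites the per-read rejection probability
  # is about 1 - (1 - 2 eps / 3)^5
  p_expect <- 1 - (1 - 2 * eps / 3)^5
  p_hat <- res$manifest$counts$rejected / res$manifest$counts$passed_filter
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(p_hat - p_expect), 4 * se)
})

test_that("empty configurations yield empty outputs, not errors", {
  cnt <- data.frame(edited_sites = "AB", count_lean = 0L, count_obob = 0L)
  expect_equal(nrow(simulate_reads(counts = cnt)), 0L)
  expect_equal(nrow(simulate_qpcr(c(lean = 5, obob = 4), n_per_group = 0L)), 0L)
})

test_that("qPCR simulation carries its designed fold change", {
  # sigma 0: fold change exactly 2^(5-4) = 2
  rec <- simulate_qpcr(c(lean = 5, obob = 4), sigma = 0, rep_sd = 0,
                       n_per_group = 4L, seed = 1)
  out <- qpcr_fold_change(rec)
  expect_equal(out$fold_change[out$group == "obob"], 2)
  # with noise the estimate stays close at a fixed seed
  rec2 <- simulate_qpcr(c(lean = 5, obob = 4), sigma = 0.2, n_per_group = 8L,
                        seed = 21)
  out2 <- qpcr_fold_change(rec2)
  expect_lt(abs(out2$fold_change[out2$group == "obob"] - 2) / 2, 0.10)
})
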