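test_that("alignment covers the cassette and scores identity over non-site bases", {
  insert <- paste0(ref$amplicon_flank5, cassette_seq(""), ref$amplicon_flank3)
  al <- align_to_reference(insert, ref)
  expect_true(al$ok)
  expect_equal(al$identity, 1)
  expect_false(anyNA(al$map[ref$site_offsets]))
  # all five sites substituted: mismatches sit only at site offsets, and the
  # non-site identity stays 1
  al2 <- align_to_reference(paste0("CCTT", cassette_seq("ABECD"), "GGAA"), ref)
  expect_true(al2$ok)
  expect_equal(al2$identity, 1)
  # truncation before site E: rejected for span
  cut <- substr(cassette_seq(""), 1, ref$site_offsets[["B"]] + 1L)
  al3 <- align_to_reference(paste0(ref$amplicon_flank5, cut), ref)
  expect_false(al3$ok)
  expect_equal(al3$reason, "span")
  expect_error(align_to_reference("", ref), "empty")
})

test_that("site calls read A as unedited, G as edited, anything else ambiguous", {
  calls <- call_sites(rbind(trimmed_read("", "u"), trimmed_read("ABD", "e")))
  expect_equal(calls$status, c("classified", "classified"))
  expect_equal(unlist(calls[1, c("A", "B", "E", "C", "D")], use.names = FALSE),
               rep("unedited", 5))
  expect_equal(unlist(calls[2, c("A", "B", "E", "C", "D")], use.names = FALSE),
               c("edited", "edited", "unedited", "unedited", "edited"))

  withN <- trimmed_read("", "n")
  pos <- nchar(ref$amplicon_flank5) + ref$site_offsets[["C"]]
  substr(withN$sequence, pos, pos) <- "N"
  out <- call_sites(withN)
  expect_equal(out$C, "ambiguous")
  expect_equal(out$status, "rejected")
  expect_equal(out$reason, "ambiguous")
})

test_that("gap-free calls equal direct indexing at the site offsets", {
  set.seed(7)
  codes <- enumerate_codes()$sites
  nonsite <- setdiff(seq_len(nchar(ref$sequence)), ref$site_offsets)
  for (i in 1:40) {
    sites <- sample(codes, 1)
    seq <- cassette_seq(sites)
    # up to 2 random non-site substitutions (within the identity budget)
    for (j in sample(nonsite, sample(0:2, 1))) {
      substr(seq, j, j) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(seq, j, j)), 1)
    }
    read <- data.frame(id = "r", group = "lean",
                       sequence = paste0(ref$amplicon_flank5, seq,
                                         ref$amplicon_flank3),
                       stringsAsFactors = FALSE)
    got <- call_sites(read)
    expected <- substring(seq, ref$site_offsets, ref$site_offsets)
    expect_equal(unlist(got[1, c("A", "B", "E", "C", "D")], use.names = FALSE),
                 ifelse(expected == "A", "unedited",
                        ifelse(expected == "G", "edited", "ambiguous")))
  }
})

test_that("a 1-bp indel in a flank does not change any site call", {
  base <- trimmed_read("ABCD", "x")
  ins <- base
  ins$sequence <- paste0(substr(base$sequence, 1, 10), "A",
                         substr(base$sequence, 11, nchar(base$sequence)))
  del <- base
  del$sequence <- paste0(substr(base$sequence, 1, 9),
                         substr(base$sequence, 11, nchar(base$sequence)))
  for (rd in list(ins, del)) {
    out <- call_sites(rd)
    expect_equal(out$status, "classified")
    expect_equal(code_of(out), "ABCD")
  }
})

test_that("every read is accounted: classified + rejected = input", {
  reads <- rbind(trimmed_read("", "a"), trimmed_read("AB", "b"),
                 data.frame(id = "junk", sequence = strrep("ACGT", 40),
                            group = "a", stringsAsFactors = FALSE))
  out <- call_sites(reads)
  expect_equal(nrow(out), 3L)
  expect_equal(sum(out$status == "classified") + sum(out$status == "rejected"), 3L)
  expect_equal(out$status[3], "rejected")
})

test_that("code_of maps classified calls to their isoform code", {
  calls <- call_sites(rbind(trimmed_read(""), trimmed_read("ABECD"),
                            trimmed_read("CD")))
  expect_equal(code_of(calls), c("", "ABECD", "CD"))
  expect_equal(translate_code("CD"), "ISV")
  bad <- calls
  bad$status[1] <- "rejected"
  expect_error(code_of(bad), "classified")
})
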