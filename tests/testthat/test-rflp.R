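fx <- make_rflp_fixture()

test_that("in-silico PCR extracts the primer-to-primer amplicon", {
  primers <- fx$primers
  rc_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(primers$reverse)
  ))
  template <- paste0(primers$forward,
                     paste(rep("ACGT", 10), collapse = ""), rc_rev)
  amp <- simulate_pcr(template, primers)
  expect_equal(nchar(amp), 22 + 40 + 24)
  expect_identical(amp, template)
  # fixture template has flanks; the amplicon is the published 357 bp
  expect_identical(simulate_pcr(fx$wt_template, primers), fx$wt_amplicon)
})

test_that("PCR failure modes are explicit conditions", {
  primers <- fx$primers
  no_rev <- paste0(primers$forward, paste(rep("ACG", 20), collapse = ""))
  expect_error(simulate_pcr(no_rev, primers),
               class = "founderage_no_amplification")
  # primers planted twice -> two products
  rc_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(primers$reverse)
  ))
  cassette <- paste0(primers$forward, "ACGACGACG", rc_rev)
  double <- paste0(cassette, paste(rep("CAG", 30), collapse = ""), cassette)
  expect_error(simulate_pcr(double, primers),
               class = "founderage_nonspecific_amplification")
})

test_that("site scanning handles trivial and degenerate cases", {
  enz <- hpy188iii()
  expect_identical(find_sites("AAAA", enz), integer(0))
  expect_identical(find_sites("TCGGGA", enz), 2L)
  expect_true(enz$self_complementary)
  expect_error(restriction_enzyme("bad", "TCXNGA", 2),
               class = "founderage_input_error")
  expect_error(restriction_enzyme("bad", "TCNNGA", 7),
               class = "founderage_input_error")
})

test_that("site scanner agrees with the naive degenerate matcher", {
  enz <- hpy188iii()
  foki <- restriction_enzyme("FokI-like", "GGATG", 2) # not self-complementary
  expect_false(foki$self_complementary)
  set.seed(31)
  for (i in 1:100) {
    seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                 collapse = "")
    expect_identical(find_sites(seq, enz),
                     naive_cut_sites(seq, "TCNNGA", 2L))
    # both-strand scan: top-strand GGATG sites plus bottom-strand sites,
    # which appear as CATCC on the top strand with the mirrored offset
    both <- sort(unique(c(
      naive_cut_sites(seq, "GGATG", 2L),
      naive_cut_sites(seq, "CATCC", 3L)
    )))
    expect_identical(find_sites(seq, foki), both)
  }
})

test_that("digestion conserves length and count", {
  enz <- hpy188iii()
  # symmetric cutter used for the strand-reversal property: a cut in the
  # middle of a self-complementary site lands on the mirrored coordinate
  # of the reverse complement, so fragments reverse exactly
  centre <- restriction_enzyme("centre", "TCNNGA", 3)
  set.seed(77)
  for (i in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                 collapse = "")
    d <- digest(seq, enz)
    expect_equal(sum(fragment_lengths(d)), nchar(seq))
    expect_equal(nrow(d), attr(d, "n_sites") + 1L)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)
    ))
    expect_identical(rev(fragment_lengths(digest(rc, centre))),
                     fragment_lengths(digest(seq, centre)))
  }
  no_site <- paste(rep("ACG", 100), collapse = "")
  expect_identical(fragment_lengths(digest(no_site, enz)), 300L)
})

test_that("the amplicon fixture digests to the assay's gel patterns", {
  expect_equal(nchar(fx$wt_amplicon), 357)
  expect_equal(nchar(fx$mut_amplicon), 357)
  expect_setequal(fragment_lengths(digest(fx$wt_amplicon, fx$enzyme)),
                  c(189, 168))
  expect_setequal(fragment_lengths(digest(fx$mut_amplicon, fx$enzyme)),
                  c(168, 122, 67))
})

test_that("fragment patterns genotype-call all four gel lanes", {
  wt <- fx$wt_pattern; mut <- fx$mut_pattern
  expect_identical(genotype_from_fragments(c(357), wt, mut), "uncalled")
  expect_identical(genotype_from_fragments(c(189, 168), wt, mut), "WT/WT")
  expect_identical(genotype_from_fragments(c(168, 122, 67), wt, mut),
                   "mut/mut")
  expect_identical(genotype_from_fragments(c(189, 168, 122, 67), wt, mut),
                   "WT/mut")
  expect_identical(genotype_from_fragments(c(500), wt, mut, 2), "uncalled")
  # gel co-migration: sizes within tolerance merge into one band
  expect_identical(genotype_from_fragments(c(190, 168, 123, 67), wt, mut, 2),
                   "WT/mut")
  expect_error(genotype_from_fragments(c(100), c(100), c(101), 5),
               class = "founderage_input_error")
})
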