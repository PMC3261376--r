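test_that("IUPAC motifs parse with correct per-position base sets", {
  kr <- iupacMotif("TGATNNATKR")
  expect_s4_class(kr, "IupacMotif")
  expect_equal(length(kr), 10L)
  sets <- motifSets(kr)
  expect_setequal(sets[[5]], c("A", "C", "G", "T"))
  expect_setequal(sets[[6]], c("A", "C", "G", "T"))
  expect_setequal(sets[[9]], c("G", "T"))
  expect_setequal(sets[[10]], c("A", "G"))

  meis <- iupacMotif("tgacar", name = "Meis")
  expect_equal(motifPattern(meis), "TGACAR")
  expect_setequal(motifSets(meis)[[6]], c("A", "G"))
  expect_equal(motifName(meis), "Meis")

  expect_error(iupacMotif("TGAXNNAT"), "position 4")
  expect_error(iupacMotif(""), "non-empty")
})

test_that("scanSequence matches degenerate consensi and handles edge cases", {
  hits <- scanSequence("TGATGGATGA", "TGATNNATKR")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, 10L)
  expect_equal(hits$matched_seq, "TGATGGATGA")
  expect_equal(hits$strand, "+")

  expect_equal(nrow(scanSequence("CCCCCCCCCC", "TGATNNAT", "both")), 0L)
  expect_equal(nrow(scanSequence("", "TGATNNAT")), 0L)
  expect_equal(nrow(scanSequence("TGAT", "TGATNNAT")), 0L)

  # case folding
  expect_equal(nrow(scanSequence("tgatggatga", "TGATNNATKR")), 1L)

  # ambiguous subject bases never match, even against pattern N
  expect_equal(nrow(scanSequence("TGATNNATGA", "TGATNNATKR")), 0L)

  # overlapping hits are all reported
  hits <- scanSequence("ATATATAT", "ATAT")
  expect_equal(hits$start, c(1L, 3L, 5L))
})

test_that("minus-strand hits are reported in forward coordinates, motif orientation", {
  # reverse complement of TGATGGATGA planted at positions 3-12
  seq <- paste0("CC", "TCATCCATCA", "GG")
  hits <- scanSequence(seq, "TGATNNATKR", strands = "both")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 12L)
  expect_equal(hits$matched_seq, "TGATGGATGA")
})

test_that("scanner agrees exactly with the naive all-offsets oracle", {
  set.seed(101)
  for (i in 1:1000) {
    seq <- randomSeq(sample(0:50, 1),
                     alphabet = c("A", "C", "G", "T", "N"),
                     probs = c(0.24, 0.24, 0.24, 0.24, 0.04))
    pattern <- randomPattern(sample(2:8, 1))
    strands <- sample(c("forward", "both"), 1)
    got <- scanSequence(seq, pattern, strands)
    want <- oracleScan(seq, pattern, strands)
    expect_equal(got$start, want$start,
                 info = sprintf("seq=%s pattern=%s", seq, pattern))
    expect_equal(got$strand, as.character(want$strand))
  }
})

test_that("scanner agrees with Biostrings degenerate matching on clean subjects", {
  set.seed(7)
  for (i in 1:50) {
    seq <- randomSeq(200)
    pattern <- randomPattern(6)
    got <- scanSequence(seq, pattern)$start
    want <- Biostrings::start(Biostrings::matchPattern(
      pattern, Biostrings::DNAString(seq), fixed = "subject"))
    expect_equal(got, want, info = pattern)
  }
})

test_that("hit counts on uniform sequence match the binomial expectation", {
  # TGATNNAT has 6 fixed positions: P(window match) = 4^-6, and a 1000 bp
  # sequence has 993 windows
  set.seed(202)
  n_seqs <- 5000
  p_window <- 4^-6
  n_windows <- 993
  total <- sum(vapply(seq_len(n_seqs), function(i)
    nrow(scanSequence(randomSeq(1000), "TGATNNAT")), integer(1)))
  expected <- n_seqs * n_windows * p_window
  # windows overlap, but dependence is weak; 4 binomial SEs is ample
  se <- sqrt(n_seqs * n_windows * p_window * (1 - p_window))
  expect_lt(abs(total - expected), 4 * se)
})

test_that("every hit's matched_seq re-satisfies the motif", {
  set.seed(303)
  motif <- iupacMotif("TGATNNATKR")
  for (i in 1:50) {
    seq <- randomSeq(500, probs = c(0.3, 0.2, 0.2, 0.3))
    hits <- scanSequence(seq, motif, "both")
    if (nrow(hits)) {
      for (m in hits$matched_seq) {
        expect_equal(nrow(scanSequence(m, motif)), 1L)
        expect_equal(scanSequence(m, motif)$start, 1L)
      }
    }
  }
})

test_that("both-strand scans find at least as many hits as forward-only", {
  set.seed(404)
  for (i in 1:100) {
    seq <- randomSeq(300)
    pattern <- randomPattern(6)
    expect_gte(nrow(scanSequence(seq, pattern, "both")),
               nrow(scanSequence(seq, pattern, "forward")))
  }
})

test_that("reverse complement handles degenerate codes and is an involution", {
  expect_equal(reverseComplementPattern("TGATNNATKR"), "YMATNNATCA")
  expect_equal(reverseComplementPattern("ACGT"), "ACGT")
  expect_equal(reverseComplementPattern(""), "")
  expect_error(reverseComplementPattern("ACGX"))
  set.seed(505)
  for (i in 1:100) {
    p <- randomPattern(sample(1:12, 1))
    expect_equal(reverseComplementPattern(reverseComplementPattern(p)), p)
    expect_equal(reverseComplementPattern(p), oracleRevComp(p))
  }
})

test_that("prefix/core family construction yields the canonical 24 variants", {
  fam <- generateFamily("TGATNNATKR")
  members <- motifPatterns(fam)
  expect_equal(length(members), 24L)
  expect_equal(anyDuplicated(members), 0L)
  expect_equal(members[1], "TGATNNATKR")
  expect_equal(fam@construction, "prefix_core")
  # the bundled published count table carries the canonical 24 strings
  expect_setequal(members, krFamilyCounts()$motif)

  fam8 <- generateFamily("TGATNNAT")
  expect_equal(length(fam8), 24L)
  expect_true(all(nchar(motifPatterns(fam8)) == 8L))
  # N block and core structure held fixed in place
  expect_true(all(substr(motifPatterns(fam8), 5, 6) == "NN"))

  # 4 distinct prefix letters: 4! orderings x 2 cores
  expect_equal(length(generateFamily("GCATNNAT")), 48L)
})

test_that("motifs outside the prefix/core scheme fall back to a generic family", {
  expect_error(generateFamily("TGACAR", scheme = "prefix_core"),
               "does not decompose")
  fam <- generateFamily("TGACAR")
  expect_equal(fam@construction, "generic")
  members <- motifPatterns(fam)
  expect_equal(members[1], "TGACAR")
  expect_equal(anyDuplicated(members), 0L)
  # degenerate position held fixed in place; fixed letters permuted:
  # distinct orderings of {T,G,A,C,A} = 5!/2! = 60
  expect_equal(length(members), 60L)
  expect_true(all(substr(members, 6, 6) == "R"))
})

test_that("countMotif counts occurrences over sets, per family member", {
  seqs <- c(a = "TGATGGATGAC", b = "CCCTGATGGATGA", c = "AAAA")
  fam <- generateFamily("TGATNNATKR")
  counts <- countMotif(seqs, fam)
  expect_equal(unname(counts["TGATNNATKR"]), 2L)
  expect_equal(names(counts)[1], "TGATNNATKR")
  expect_equal(countMotif(seqs, "TGATNNATKR"), 2L)
})
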