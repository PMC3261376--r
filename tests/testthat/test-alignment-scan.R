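make_aln <- function(id, rows) cneAlignment(id, rows)

test_that("CneAlignment validity enforces shape and content", {
  expect_error(cneAlignment("x", c(a = "ACGT")), ">= 2 rows")
  expect_error(cneAlignment("x", c(a = "ACGT", b = "ACG")), "same number")
  expect_error(cneAlignment("x", c(a = "----", b = "ACGT")), "non-gap")
  aln <- cneAlignment("x", c(hs = "ACG-T", dr = "AC--T"))
  expect_equal(alignmentWidth(aln), 5L)
  expect_equal(speciesNames(aln), c("hs", "dr"))
  expect_equal(length(aln), 2L)
})

test_that("conservedScan requires a gap-free window matching in every row", {
  pad <- function(core) paste0("CCCC", core, "CCCC")
  rows <- c(human = pad("TGATGGAT"), fugu = pad("TGATCAAT"),
            zebrafish = pad("TGATTTAT"))
  aln <- make_aln("cne1", rows)
  hits <- conservedScan(aln, "TGATNNAT")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$column_start, 5L)
  expect_equal(hits$column_end, 12L)
  expect_equal(hits$human, "TGATGGAT")
  expect_equal(hits$zebrafish, "TGATTTAT")

  # one row mismatching kills the hit
  rows2 <- rows
  rows2["fugu"] <- pad("TGATCAAA")
  expect_equal(nrow(conservedScan(make_aln("cne2", rows2), "TGATNNAT")), 0L)

  # a gap inside the window kills the hit even if letters would match
  rows3 <- c(human = paste0("CCCC", "TGAT-GGAT", "CCC"),
             fugu  = paste0("CCCC", "TGATCGGAT", "CCC"),
             zebrafish = paste0("CCCC", "TGATAGGAT", "CCC"))
  expect_equal(nrow(conservedScan(make_aln("cne3", rows3), "TGATNNAT")), 0L)
})

test_that("conserved hits on both strands are distinct and strand-consistent", {
  core_rc <- "TCATCCATCA"  # reverse complement of TGATGGATGA
  rows <- c(a = paste0("GG", core_rc, "GG"), b = paste0("GG", core_rc, "GG"))
  hits <- conservedScan(make_aln("cne4", rows), "TGATNNATKR", strands = "both")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$a, "TGATGGATGA")
})

test_that("two identical ungapped rows reproduce the single-sequence scan", {
  set.seed(11)
  for (i in 1:25) {
    seq <- randomSeq(80)
    aln <- make_aln(paste0("a", i), c(x = seq, y = seq))
    ch <- conservedScan(aln, "TGATNNAT", strands = "both")
    sh <- scanSequence(seq, "TGATNNAT", strands = "both")
    expect_equal(ch$column_start, sh$start)
    expect_equal(ch$strand, sh$strand)
  }
})

test_that("conserved count never exceeds any row's ungapped scan count", {
  set.seed(12)
  for (i in 1:500) {
    aln <- randomAlignment(paste0("r", i), n_rows = sample(2:4, 1),
                           n_cols = sample(10:60, 1))
    pattern <- randomPattern(sample(2:6, 1))
    n_cons <- nrow(conservedScan(aln, pattern))
    per_row <- vapply(alignmentRows(aln), function(r)
      nrow(scanSequence(gsub("-", "", r), pattern)), integer(1))
    expect_lte(n_cons, min(per_row))
  }
})

test_that("column shuffling permutes columns, preserving vertical content", {
  # single-column alignment: only one permutation exists
  one <- make_aln("one", c(a = "A", b = "C"))
  expect_equal(alignmentRows(shuffleColumns(one, seed = 1)),
               alignmentRows(one))

  set.seed(13)
  for (i in 1:100) {
    aln <- randomAlignment(paste0("s", i), n_rows = 3,
                           n_cols = sample(5:50, 1))
    shuf <- shuffleColumns(aln)
    expect_equal(alignmentWidth(shuf), alignmentWidth(aln))
    expect_equal(speciesNames(shuf), speciesNames(aln))
    col_vectors <- function(a) {
      m <- do.call(rbind, strsplit(unname(alignmentRows(a)), ""))
      sort(apply(m, 2, paste, collapse = ""))
    }
    # multiset of column vectors is invariant
    expect_equal(col_vectors(shuf), col_vectors(aln))
    # per-row composition (including gaps) is invariant
    for (r in seq_len(length(aln))) {
      expect_equal(sort(strsplit(alignmentRows(shuf)[[r]], "")[[1]]),
                   sort(strsplit(alignmentRows(aln)[[r]], "")[[1]]))
    }
  }
})

test_that("column shuffling is deterministic for a given seed", {
  aln <- randomAlignment("d", n_rows = 4, n_cols = 60)
  expect_equal(alignmentRows(shuffleColumns(aln, seed = 99)),
               alignmentRows(shuffleColumns(aln, seed = 99)))
})

test_that("alignmentNull matches explicit shuffle-and-scan replicates", {
  set.seed(14)
  gen <- generateAlignmentSet(8, nSpecies = 3, plantedMotif = "TGATNNAT",
                              plantedDensity = 1, substitutionRate = 0.05,
                              gapRate = 0.02, seed = 21)
  nl <- alignmentNull(gen$alignments, "TGATNNAT", nReplicates = 5, seed = 7)
  manual <- vapply(1:5, function(r) {
    set.seed(7 + r)
    sum(vapply(gen$alignments, function(a)
      nrow(conservedScan(shuffleColumns(a), "TGATNNAT")), integer(1)))
  }, integer(1))
  expect_equal(nullCounts(nl), manual)
  expect_equal(observedCount(nl),
               sum(vapply(gen$alignments, function(a)
                 nrow(conservedScan(a, "TGATNNAT")), integer(1))))
})

test_that("alignmentNull is reproducible bit-for-bit and detects planted signal", {
  gen <- generateAlignmentSet(20, nSpecies = 4, plantedMotif = "TGATNNAT",
                              plantedDensity = 1, substitutionRate = 0,
                              gapRate = 0, seed = 31)
  n1 <- alignmentNull(gen$alignments, "TGATNNAT", nReplicates = 100, seed = 5)
  n2 <- alignmentNull(gen$alignments, "TGATNNAT", nReplicates = 100, seed = 5)
  expect_identical(nullCounts(n1), nullCounts(n2))
  expect_identical(observedCount(n1), observedCount(n2))

  # planted, scrubbed signal: observed equals truth, shuffled replicates
  # essentially never reassemble the motif in all rows
  expect_equal(observedCount(n1), nrow(gen$truth))
  expect_gt(foldEnrichment(n1), 10)
})

test_that("alignmentNull conventions: absent motif and empty input", {
  # observed 0 but shuffling can assemble the motif: fold = 0
  rows <- c(a = "AAAATTTT", b = "AAAATTTT")
  nl <- alignmentNull(list(make_aln("z", rows)), "TA", nReplicates = 200,
                      seed = 3)
  expect_equal(observedCount(nl), 0L)
  expect_gt(mean(nullCounts(nl)), 0)
  expect_equal(foldEnrichment(nl), 0)

  expect_error(alignmentNull(list(), "TGATNNAT"), "empty")
})
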