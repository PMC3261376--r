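test_that("family enrichment reproduces the published CONDOR statistics", {
  tab <- krFamilyCounts()
  counts <- setNames(tab$condor_cnes, tab$motif)
  res <- familyEnrichment(counts, datasetName = "CONDOR CNEs")
  # closed-form check: mean/SD over all 24 counts incl. the original,
  # sample SD, one-sided upper-tail normal p
  expect_equal(res@mean, sum(counts) / 24)
  expect_equal(res@mean, 165.375)
  expect_equal(res@sd, sd(counts))
  expect_equal(res@sd, 102.748, tolerance = 1e-5)
  expect_equal(zScore(res), (562 - mean(counts)) / sd(counts))
  expect_equal(zScore(res), 3.86015, tolerance = 1e-5)
  expect_equal(pValue(res), pnorm(zScore(res), lower.tail = FALSE))
  expect_equal(pValue(res), 5.665e-05, tolerance = 1e-3)
  expect_true(isSignificant(res))
  expect_equal(observedCount(res), 562)
})

test_that("family enrichment handles degenerate and invalid inputs", {
  res <- familyEnrichment(rep(5, 10), "flat")
  expect_true(is.na(zScore(res)))
  expect_true(is.na(pValue(res)))
  expect_false(isSignificant(res))
  expect_match(res@note, "sd = 0")

  expect_error(familyEnrichment(c(1, 2)), "at least 3")
  expect_error(familyEnrichment(c(-1, 2, 3)), "non-negative")
})

test_that("family z-score is invariant under common positive affine rescaling", {
  set.seed(21)
  counts <- c(40, rpois(23, 10))
  z0 <- zScore(familyEnrichment(counts))
  for (i in 1:20) {
    a <- runif(1, 0.1, 50)
    b <- runif(1, 0, 100)
    expect_equal(zScore(familyEnrichment(a * counts + b)), z0)
  }
})

test_that("p is one-sided upper tail: decreasing in z, 0.5 at z = 0", {
  # observed equal to the mean of the collection gives z = 0, p = 0.5
  res0 <- familyEnrichment(c(10, 5, 15, 12, 8))
  expect_equal(zScore(res0), 0)
  expect_equal(pValue(res0), 0.5)

  zs <- ps <- numeric(20)
  set.seed(22)
  base <- rpois(23, 20)
  for (i in 1:20) {
    r <- familyEnrichment(c(20 + 3 * i, base))
    zs[i] <- zScore(r)
    ps[i] <- pValue(r)
  }
  expect_true(all(diff(zs) > 0))
  expect_true(all(diff(ps) < 0))
})

test_that("density chi-square has 1 df, no continuity correction, and is symmetric", {
  d <- densityChiSquare(64, 112000, 85, 238000)
  # closed-form oracle: expected counts proportional to lengths
  e <- (64 + 85) * c(112000, 238000) / 350000
  expect_equal(d@chiSquare, sum((c(64, 85) - e)^2 / e))
  expect_equal(pValue(d), pchisq(d@chiSquare, 1, lower.tail = FALSE))
  expect_equal(d@df, 1L)

  # symmetry under swapping the two classes
  d2 <- densityChiSquare(85, 238000, 64, 112000)
  expect_equal(d2@chiSquare, d@chiSquare)
  expect_equal(pValue(d2), pValue(d))
  expect_equal(d2@rateRatio, 1 / d@rateRatio)

  # exactly proportional densities: statistic 0, p 1
  d0 <- densityChiSquare(10, 1000, 20, 2000)
  expect_equal(d0@chiSquare, 0)
  expect_equal(pValue(d0), 1)
  expect_equal(d0@rateRatio, 1)

  expect_error(densityChiSquare(0, 100, 0, 100), "zero total")
  expect_error(densityChiSquare(1, 0, 1, 100))
})

test_that("markov0Shuffle draws i.i.d. bases with the requested composition", {
  expect_equal(markov0Shuffle("GGGGG", c(1, 0, 0, 0)), "AAAAA")
  expect_equal(nchar(markov0Shuffle(strrep("A", 137), rep(0.25, 4))), 137L)
  expect_equal(markov0Shuffle("", rep(0.25, 4)), "")
  expect_identical(markov0Shuffle(strrep("A", 50), rep(0.25, 4), seed = 9),
                   markov0Shuffle(strrep("A", 50), rep(0.25, 4), seed = 9))
  expect_error(markov0Shuffle("ACGT", c(0.5, 0.5, 0.5, 0.5)), "sum to 1")

  probs <- c(0.3, 0.2, 0.2, 0.3)
  out <- markov0Shuffle(strrep("A", 1e6), probs, seed = 23)
  freq <- baseFrequencies(out)
  se <- sqrt(probs * (1 - probs) / 1e6)
  expect_true(all(abs(freq - probs) < 3 * se))
})

test_that("baseFrequencies pools ACGT content and excludes everything else", {
  expect_equal(baseFrequencies("ACGT"),
               c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_equal(baseFrequencies("AAAT"), c(A = 0.75, C = 0, G = 0, T = 0.25))
  # Ns and gaps leave numerator and denominator
  expect_equal(baseFrequencies(c("AANN--", "AT")),
               c(A = 0.6, C = 0, G = 0, T = 0.2) / 0.8)
  expect_error(baseFrequencies("NNNN"), "no A/C/G/T")

  set.seed(24)
  probs <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  cne <- generateCneSet(200, baseProbs = probs, seed = 25)
  n <- sum(nchar(cne$seqs))
  freq <- baseFrequencies(cne$seqs)
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(freq - probs) < 3 * se))
})

test_that("locus Markov-0 control counts match brute-force regeneration", {
  seqs <- c(a = strrep("ACGT", 10), b = strrep("TTAA", 8))
  motif <- iupacMotif("TGATNNAT")
  probs <- rep(0.25, 4)
  le <- locusEnrichment(seqs, motif, probs, nSets = 30, seed = 77)
  # replicate the engine's draws: one stream, sets drawn consecutively,
  # then count with the single-sequence scanner on materialised strings
  set.seed(77)
  B <- sum(nchar(seqs))
  brute <- vapply(1:30, function(r) {
    x <- sample.int(4, B, replace = TRUE, prob = probs)
    bases <- c("A", "C", "G", "T")[x]
    s1 <- paste(bases[1:40], collapse = "")
    s2 <- paste(bases[41:72], collapse = "")
    nrow(scanSequence(s1, motif)) + nrow(scanSequence(s2, motif))
  }, integer(1))
  expect_equal(le@controlMean, mean(brute))
  expect_equal(le@controlSd, sd(brute))
})

test_that("locusEnrichment recovers a planted signal and rejects degenerate input", {
  set.seed(26)
  cne <- generateCneSet(20, lengthMean = 120, lengthSd = 0,
                        baseProbs = rep(0.25, 4),
                        plantedMotif = "TGATNNATKR", plantedDensity = 1,
                        seed = 27)
  le <- locusEnrichment(cne$seqs, "TGATNNATKR", rep(0.25, 4),
                        nSets = 1000, seed = 28, locus = "planted")
  expect_equal(observedCount(le), nrow(cne$truth))
  expect_gt(zScore(le), 5)
  expect_lt(pValue(le), 1e-6)
  expect_equal(le@hitsPerKb, observedCount(le) / (le@totalBp / 1000))

  expect_error(locusEnrichment(cne$seqs, "TGATNNATKR", rep(0.25, 4),
                               nSets = 1), ">= 2")
  expect_error(locusEnrichment(character(0), "TGATNNATKR", rep(0.25, 4)),
               "empty locus")
})
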