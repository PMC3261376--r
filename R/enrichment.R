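#' Shuffled-motif-family enrichment z-score
#'
#' Compares the occurrence count of a motif with the counts of its shuffled
#' family members in the same dataset. The mean and standard deviation are
#' computed over the full count collection *including* the original
#' motif's count, with the sample (n-1) SD; the z-score is for the original
#' motif and the p-value is the one-sided upper-tail standard normal
#' probability (enrichment only). When all counts are equal the SD is zero,
#' z and p are undefined and the result is flagged not significant.
#'
#' @param counts numeric vector of occurrence counts, the original motif's
#'   count first; at least 3 entries. Names (if present) are taken as the
#'   member patterns.
#' @param datasetName label recorded in the result.
#' @param motifName label for the original motif; defaults to
#'   `names(counts)[1]`.
#' @param strands strand convention that produced the counts (recorded,
#'   not used in the computation).
#' @return an [EnrichmentResult-class] with `nullKind = "motif_family"`.
#' @examples
#' fam <- generateFamily("TGATNNATKR")
#' set.seed(1)
#' seqs <- generateCneSet(50, plantedMotif = "TGATNNATKR",
#'                        plantedDensity = 0.5, seed = 1)$seqs
#' res <- familyEnrichment(countMotif(seqs, fam), "synthetic")
#' zScore(res)
#' @export
familyEnrichment <- function(counts, datasetName = "", motifName = NULL,
                             strands = "forward") {
  stopifnot(is.numeric(counts))
  if (length(counts) < 3L)
    stop("need at least 3 counts (original + shuffled members)")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(motifName))
    motifName <- if (!is.null(names(counts))) names(counts)[1L] else "motif"
  m <- mean(counts)
  s <- stats::sd(counts)
  note <- ""
  if (s > 0) {
    z <- (counts[[1L]] - m) / s
    p <- stats::pnorm(z, lower.tail = FALSE)
  } else {
    z <- NA_real_
    p <- NA_real_
    note <- "all counts equal: sd = 0, z undefined; reported not significant"
  }
  methods::new("EnrichmentResult", motifName = motifName,
               datasetName = datasetName, observed = counts[[1L]],
               nullCounts = unname(as.numeric(counts)), mean = m, sd = s,
               z = z, p = p, nullKind = "motif_family",
               strands = .normStrands(strands), note = note)
}

#' @rdname result-accessors
#' @export
setMethod("observedCount", "EnrichmentResult", function(x) x@observed)

#' @rdname result-accessors
#' @export
setMethod("nullCounts", "EnrichmentResult", function(x) x@nullCounts)

#' @rdname result-accessors
#' @export
setMethod("zScore", "EnrichmentResult", function(x) x@z)

#' @rdname result-accessors
#' @export
setMethod("pValue", "EnrichmentResult", function(x) x@p)

#' @rdname result-accessors
#' @export
setMethod("isSignificant", "EnrichmentResult", function(x, alpha = 0.05) {
  !is.na(x@p) && x@p <= alpha
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult [%s]: motif %s in '%s' (%s strand)\n",
              object@nullKind, object@motifName, object@datasetName,
              object@strands))
  cat(sprintf("  observed %g; null mean %.2f, sd %.2f (n = %d)\n",
              object@observed, object@mean, object@sd,
              length(object@nullCounts)))
  if (is.na(object@z)) {
    cat("  z undefined (sd = 0); N/S\n")
  } else {
    cat(sprintf("  z = %.2f, one-sided p = %.3g%s\n", object@z, object@p,
                if (object@p > 0.05) " (N/S)" else ""))
  }
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

#' @describeIn EnrichmentResult-class one-row data.frame summary.
#' @param x an `EnrichmentResult`.
#' @param row.names,optional,... passed through (unused).
#' @export
setMethod("as.data.frame", "EnrichmentResult",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(motif_name = x@motifName, dataset = x@datasetName,
             observed = x@observed, mean = x@mean, sd = x@sd,
             z = x@z, p = x@p, null_kind = x@nullKind,
             strands = x@strands, n_null = length(x@nullCounts),
             stringsAsFactors = FALSE)
})

#' Chi-square comparison of motif densities between two element classes
#'
#' Tests whether motif occurrences split between two sequence classes in
#' proportion to their total lengths: a 1-df goodness-of-fit chi-square
#' with expected counts proportional to lengths and no continuity
#' correction (via [stats::chisq.test()]).
#'
#' @param countA,countB observed occurrence counts (total > 0).
#' @param lengthA,lengthB total sequence lengths in bp (> 0).
#' @return a [DensityComparison-class].
#' @examples
#' densityChiSquare(64, 112000, 85, 238000)  # p ~ 0.0042
#' @export
densityChiSquare <- function(countA, lengthA, countB, lengthB) {
  stopifnot(lengthA > 0, lengthB > 0, countA >= 0, countB >= 0)
  if (countA + countB == 0) stop("zero total count: no test possible")
  ct <- suppressWarnings(
    stats::chisq.test(c(countA, countB),
                      p = c(lengthA, lengthB) / (lengthA + lengthB)))
  methods::new("DensityComparison",
               countA = as.numeric(countA), countB = as.numeric(countB),
               lengthA = as.numeric(lengthA), lengthB = as.numeric(lengthB),
               chiSquare = unname(ct$statistic), df = 1L,
               p = unname(ct$p.value),
               rateRatio = (countA / lengthA) / (countB / lengthB))
}

#' @rdname result-accessors
#' @export
setMethod("pValue", "DensityComparison", function(x) x@p)

#' @rdname result-accessors
#' @export
setMethod("isSignificant", "DensityComparison",
          function(x, alpha = 0.05) x@p <= alpha)

setMethod("show", "DensityComparison", function(object) {
  cat(sprintf(
    "DensityComparison: %g hits / %g bp vs %g hits / %g bp\n  rate ratio %.3f; chi-square %.3f (df 1), p = %.3g\n",
    object@countA, object@lengthA, object@countB, object@lengthB,
    object@rateRatio, object@chiSquare, object@p))
})

#' Pooled mononucleotide frequencies of a sequence set
#'
#' Relative frequencies of A, C, G, T pooled over all sequences; characters
#' outside `A,C,G,T` (gaps, Ns) are excluded from both numerator and
#' denominator. These are the transition probabilities of the order-0
#' Markov background model.
#'
#' @param seqs character vector, list or [Biostrings::DNAStringSet].
#' @return named numeric vector `c(A=,C=,G=,T=)` summing to 1.
#' @examples
#' baseFrequencies(c("ACGT", "AAAT"))
#' @export
baseFrequencies <- function(seqs) {
  seqs <- .asSeqVector(seqs)
  codes <- .seqCodes(paste(seqs, collapse = ""))
  codes <- codes[codes > 0L]
  if (!length(codes)) stop("no A/C/G/T content in input")
  tab <- tabulate(codes, nbins = 4L)
  stats::setNames(tab / sum(tab), c("A", "C", "G", "T"))
}

.checkProbs <- function(probs) {
  stopifnot(is.numeric(probs), length(probs) == 4L)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop("base probabilities must be non-negative and sum to 1")
  if (!is.null(names(probs))) {
    stopifnot(setequal(names(probs), c("A", "C", "G", "T")))
    probs <- probs[c("A", "C", "G", "T")]
  }
  unname(probs)
}

#' Markov order-0 sequence shuffle
#'
#' Regenerates a sequence of the same length with bases drawn i.i.d. from
#' the supplied mononucleotide probabilities — the locus-level null model
#' for motif counting (composition preserved in expectation, all
#' positional structure destroyed).
#'
#' @param seq character string (only its length is used).
#' @param probs probabilities for A, C, G, T (see [baseFrequencies()]).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return character string of the same length as `seq`.
#' @export
markov0Shuffle <- function(seq, probs, seed = NULL) {
  probs <- .checkProbs(probs)
  if (!is.null(seed)) set.seed(seed)
  n <- nchar(as.character(seq))
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Fast control-count engine: counts motif occurrences in nSets i.i.d.
# regenerated copies of a sequence set, without materialising strings.
# `allowed` is a list of allowed-matrices (one per strand scanned).
.markovNullCounts <- function(widths, allowed, probs, nSets,
                              chunk_sets = 100L) {
  L <- nrow(allowed[[1L]])
  B <- sum(widths)
  # valid window starts within one concatenated set (no window crosses a
  # sequence boundary)
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  mask <- logical(B)
  for (i in seq_along(widths)) {
    if (widths[i] >= L) mask[offsets[i] + seq_len(widths[i] - L + 1L)] <- TRUE
  }
  counts <- integer(nSets)
  done <- 0L
  while (done < nSets) {
    m <- min(chunk_sets, nSets - done)
    x <- sample.int(4L, m * B, replace = TRUE, prob = probs)
    n <- length(x)
    total_hits <- rep(FALSE, n - L + 1L)
    for (al in allowed) {
      v <- al[1L, x[1:(n - L + 1L)] + 1L]
      if (L > 1L) for (k in 2:L) v <- v & al[k, x[k:(n - L + k)] + 1L]
      starts <- which(v & rep(mask, m)[1:(n - L + 1L)])
      if (length(starts)) {
        set_idx <- (starts - 1L) %/% B + 1L
        counts[done + seq_len(m)] <- counts[done + seq_len(m)] +
          tabulate(set_idx, nbins = m)
      }
    }
    done <- done + m
  }
  counts
}

#' Per-locus motif enrichment against the Markov-0 null
#'
#' Counts motif occurrences over all CNEs of one gene locus and compares
#' the total with counts in `nSets` control sets, each consisting of
#' same-length Markov order-0 regenerations of every locus sequence using
#' the *global* base composition of the full CNE collection (supply
#' `globalProbs` from [baseFrequencies()] on the whole set, not the locus).
#' The z-score uses the sample (n-1) SD of the control counts and the
#' p-value is one-sided upper tail normal.
#'
#' @param seqs named character vector / [Biostrings::DNAStringSet] of the
#'   locus CNE sequences.
#' @param motif an [IupacMotif-class] or IUPAC string.
#' @param globalProbs base probabilities for A, C, G, T.
#' @param nSets number of control sets (>= 2; the SD of a single control
#'   count is undefined).
#' @param seed integer seed for the control-set RNG.
#' @param strands `"forward"` or `"both"`.
#' @param locus locus/gene label recorded in the result.
#' @return a [LocusEnrichment-class].
#' @export
locusEnrichment <- function(seqs, motif, globalProbs, nSets = 1000L,
                            seed = 1L, strands = "forward", locus = "") {
  seqs <- .asSeqVector(seqs)
  if (!length(seqs)) stop("empty locus: no sequences supplied")
  motif <- .asMotif(motif)
  strands <- .normStrands(strands)
  nSets <- as.integer(nSets)
  if (nSets < 2L)
    stop("nSets must be >= 2: the standard deviation of a single ",
         "control count is undefined")
  probs <- .checkProbs(globalProbs)

  observed <- countMotif(seqs, motif, strands)
  patterns <- motif@pattern
  if (strands == "both")
    patterns <- c(patterns, reverseComplementPattern(motif@pattern))
  allowed <- lapply(patterns, .allowedMatrix)

  set.seed(seed)
  ctrl <- .markovNullCounts(nchar(seqs), allowed, probs, nSets)
  m <- mean(ctrl)
  s <- stats::sd(ctrl)
  z <- if (s > 0) (observed - m) / s else NA_real_
  p <- if (is.na(z)) NA_real_ else stats::pnorm(z, lower.tail = FALSE)
  total_bp <- sum(nchar(seqs))
  methods::new("LocusEnrichment", locus = as.character(locus),
               motifName = motif@name, strands = strands,
               observed = as.integer(observed), totalBp = as.integer(total_bp),
               hitsPerKb = observed / (total_bp / 1000),
               controlMean = m, controlSd = s, z = z, p = p,
               nSets = nSets, seed = as.integer(seed))
}

#' @rdname result-accessors
#' @export
setMethod("observedCount", "LocusEnrichment", function(x) x@observed)

#' @rdname result-accessors
#' @export
setMethod("zScore", "LocusEnrichment", function(x) x@z)

#' @rdname result-accessors
#' @export
setMethod("pValue", "LocusEnrichment", function(x) x@p)

#' @rdname result-accessors
#' @export
setMethod("isSignificant", "LocusEnrichment", function(x, alpha = 0.05) {
  !is.na(x@p) && x@p <= alpha
})

setMethod("show", "LocusEnrichment", function(object) {
  cat(sprintf(
    "LocusEnrichment '%s': motif %s, %d hits in %d bp (%.2f per kb)\n  control mean %.2f, sd %.2f (%d sets); z = %.2f, p = %.3g\n",
    object@locus, object@motifName, object@observed, object@totalBp,
    object@hitsPerKb, object@controlMean, object@controlSd, object@nSets,
    object@z, object@p))
})

#' @describeIn LocusEnrichment-class one-row data.frame summary.
#' @param x a `LocusEnrichment`.
#' @param row.names,optional,... passed through (unused).
#' @export
setMethod("as.data.frame", "LocusEnrichment",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(locus = x@locus, motif_name = x@motifName,
             observed = x@observed, total_bp = x@totalBp,
             hits_per_kb = x@hitsPerKb, control_mean = x@controlMean,
             control_sd = x@controlSd, z = x@z, p = x@p,
             n_sets = x@nSets, stringsAsFactors = FALSE)
})
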