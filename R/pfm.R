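#' Build a position frequency matrix from motif hits
#'
#' Tabulates per-position base counts over the matched windows of a set of
#' hits of one motif, each extended by `flank3prime` bases immediately
#' downstream (3') of the motif in motif orientation: for a `+` hit the
#' bases after `end`, for a `-` hit the (reverse-complemented) bases before
#' `start`. Hits whose flank runs off the element end are dropped and
#' counted in `nDropped`. With the default 2-base flank, 8-mer Pbx-Hox
#' `TGATNNAT` hits yield the 10-column matrix in which positions 9-10
#' expose the K/R bias.
#'
#' For conserved alignment hits, extract the designated reference species'
#' row (ungapped) and its hits first, then call this function.
#'
#' @param hits hit data.frame from [scanSequence()]/[scanSet()].
#' @param seqs the source sequences (named; every `element_id` present).
#' @param flank3prime number of downstream flanking bases (default 2).
#' @return a [PositionFrequencyMatrix-class].
#' @export
buildPfm <- function(hits, seqs, flank3prime = 2L) {
  if (!nrow(hits)) stop("empty hit list: no sites to tabulate")
  if (length(unique(hits$motif_name)) > 1L)
    stop("hits must come from a single motif")
  seqs <- .asSeqVector(seqs)
  missing <- setdiff(unique(hits$element_id), names(seqs))
  if (length(missing))
    stop("sequences missing for elements: ", paste(missing, collapse = ", "))
  flank3prime <- as.integer(flank3prime)
  stopifnot(flank3prime >= 0L)

  widths <- nchar(seqs)[hits$element_id]
  keep <- ifelse(hits$strand == "+",
                 hits$end + flank3prime <= widths,
                 hits$start - flank3prime >= 1L)
  dropped <- sum(!keep)
  kept <- hits[keep, , drop = FALSE]
  if (!nrow(kept)) stop("all hits dropped: flank runs off every element")

  windows <- ifelse(
    kept$strand == "+",
    substring(seqs[kept$element_id], kept$start, kept$end + flank3prime),
    vapply(substring(seqs[kept$element_id],
                     kept$start - flank3prime, kept$end),
           reverseComplementPattern, character(1L), USE.NAMES = FALSE))

  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(windows))
  counts <- matrix(0L, nrow = 4L, ncol = nchar(windows[1L]),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (b in c("A", "C", "G", "T")) {
    if (b %in% rownames(cm)) counts[b, ] <- cm[b, ]
  }
  methods::new("PositionFrequencyMatrix", counts = counts,
               nSites = nrow(kept), nDropped = as.integer(dropped),
               source = sprintf("motif %s; %d sites; 3' flank %d",
                                kept$motif_name[1L], nrow(kept), flank3prime))
}

#' Per-position frequencies and information content for logo plotting
#'
#' Converts a PFM into the table a sequence-logo renderer needs: relative
#' base frequencies per position and Shannon information content
#' `2 - H` bits, where `H = -sum(f * log2(f))` (0 for a uniform column,
#' 2 for a single-base column).
#'
#' @param pfm a [PositionFrequencyMatrix-class] with at least one site.
#' @return data.frame with columns `position`, `A`, `C`, `G`, `T`
#'   (frequencies) and `information` (bits).
#' @export
pfmToLogoTable <- function(pfm) {
  stopifnot(methods::is(pfm, "PositionFrequencyMatrix"))
  if (pfm@nSites < 1L) stop("PFM has no sites")
  totals <- colSums(pfm@counts)
  freq <- sweep(pfm@counts, 2L, pmax(totals, 1L), "/")
  info <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  out <- data.frame(position = seq_len(ncol(freq)), t(freq),
                    information = info)
  rownames(out) <- NULL
  out
}

#' @describeIn PositionFrequencyMatrix-class per-position frequency matrix
#'   (columns sum to 1).
#' @param x a `PositionFrequencyMatrix`.
#' @export
pfmFrequencies <- function(x) {
  stopifnot(methods::is(x, "PositionFrequencyMatrix"))
  sweep(x@counts, 2L, pmax(colSums(x@counts), 1L), "/")
}

#' @describeIn PositionFrequencyMatrix-class raw count matrix.
#' @export
pfmCounts <- function(x) {
  stopifnot(methods::is(x, "PositionFrequencyMatrix"))
  x@counts
}

setMethod("show", "PositionFrequencyMatrix", function(object) {
  cat(sprintf("PositionFrequencyMatrix: %d positions, %d sites (%d dropped)\n  %s\n",
              ncol(object@counts), object@nSites, object@nDropped,
              object@source))
  print(object@counts)
})

#' Write a PFM as a tab-separated matrix
#'
#' Rows A, C, G, T; one column per position; a `base` header column.
#'
#' @param pfm a [PositionFrequencyMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePfm <- function(pfm, path) {
  stopifnot(methods::is(pfm, "PositionFrequencyMatrix"))
  m <- pfm@counts
  df <- data.frame(base = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("base", paste0("pos", seq_len(ncol(m))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a PFM in MEME minimal motif format
#'
#' Emits a single-motif MEME (version 4) minimal text block with
#' letter-probability rows, for interoperability with downstream motif
#' tools.
#'
#' @param pfm a [PositionFrequencyMatrix-class].
#' @param path output file.
#' @param name motif name for the MEME block.
#' @param background background base frequencies (default uniform).
#' @return `path`, invisibly.
#' @export
writeMeme <- function(pfm, path, name = "motif",
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(methods::is(pfm, "PositionFrequencyMatrix"))
  background <- .checkProbs(background)
  freq <- pfmFrequencies(pfm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background[1], background[2], background[3],
                       background[4]), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(freq), pfm@nSites)), con)
  for (j in seq_len(ncol(freq))) {
    writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                       freq["A", j], freq["C", j], freq["G", j],
                       freq["T", j]), con)
  }
  invisible(path)
}
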