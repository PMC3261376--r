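#' Parse an IUPAC consensus motif
#'
#' @param pattern motif string over the IUPAC alphabet
#'   (`A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N`), case-insensitive.
#' @param name optional label; defaults to the upper-cased pattern.
#' @return an [IupacMotif-class].
#' @examples
#' kr <- iupacMotif("TGATNNATKR")
#' motifSets(kr)[[9]]   # K -> G, T
#' meis <- iupacMotif("TGACAR", name = "Meis")
#' @export
iupacMotif <- function(pattern, name = NULL) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  pattern <- toupper(pattern)
  if (!nzchar(pattern)) stop("motif pattern must be non-empty")
  .validateIupac(pattern, "motif")
  if (is.null(name)) name <- pattern
  methods::new("IupacMotif", pattern = pattern, name = as.character(name))
}

#' @rdname motif-accessors
#' @export
setMethod("motifPattern", "IupacMotif", function(x) x@pattern)

#' @rdname motif-accessors
#' @export
setMethod("motifName", "IupacMotif", function(x) x@name)

#' @rdname motif-accessors
#' @export
setMethod("motifSets", "IupacMotif", function(x) {
  chars <- strsplit(x@pattern, "", fixed = TRUE)[[1L]]
  stats::setNames(.IUPAC_SETS[chars], chars)
})

#' @describeIn IupacMotif-class motif length in bases.
#' @param x an `IupacMotif`.
#' @export
setMethod("length", "IupacMotif", function(x) nchar(x@pattern))

setMethod("show", "IupacMotif", function(object) {
  cat(sprintf("IupacMotif '%s': %s (%d bp)\n",
              object@name, object@pattern, nchar(object@pattern)))
})

.asMotif <- function(motif) {
  if (methods::is(motif, "IupacMotif")) motif else iupacMotif(motif)
}

.normStrands <- function(strands) {
  match.arg(strands, c("forward", "both"))
}

#' Scan a single DNA sequence for a degenerate motif
#'
#' Exact degenerate-consensus matching: every start offset whose window
#' satisfies all motif positions yields one hit; overlapping hits are all
#' reported. Ambiguous subject characters (anything outside `A,C,G,T`,
#' including `N`) never satisfy any motif position. With
#' `strands = "both"`, the motif is additionally matched against the
#' reverse complement; minus-strand hits are reported in forward element
#' coordinates with `matched_seq` in motif orientation. Hits are sorted by
#' `start`, then strand (`+` before `-`).
#'
#' @param seq a character string or [Biostrings::DNAString] (case folded to
#'   upper). An empty or too-short sequence yields zero hits, not an error.
#' @param motif an [IupacMotif-class] or IUPAC string.
#' @param strands `"forward"` (default) or `"both"`.
#' @param element_id identifier recorded in the hit table.
#' @return data.frame with columns `element_id`, `start`, `end` (1-based,
#'   inclusive), `strand`, `motif_name`, `matched_seq`.
#' @examples
#' scanSequence("TGATGGATGA", "TGATNNATKR")
#' @export
scanSequence <- function(seq, motif, strands = "forward",
                         element_id = "seq") {
  motif <- .asMotif(motif)
  strands <- .normStrands(strands)
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1L)
  L <- length(motif)
  codes <- .seqCodes(seq)
  fwd <- .matchStarts(codes, .allowedMatrix(motif@pattern))
  hits <- data.frame(
    element_id = rep(element_id, length(fwd)),
    start = fwd, end = fwd + L - 1L,
    strand = rep("+", length(fwd)),
    motif_name = rep(motif@name, length(fwd)),
    matched_seq = if (length(fwd)) substring(seq, fwd, fwd + L - 1L)
                  else character(0),
    stringsAsFactors = FALSE)
  if (strands == "both") {
    rc <- .matchStarts(codes, .allowedMatrix(reverseComplementPattern(motif@pattern)))
    if (length(rc)) {
      rev_hits <- data.frame(
        element_id = rep(element_id, length(rc)),
        start = rc, end = rc + L - 1L,
        strand = rep("-", length(rc)),
        motif_name = rep(motif@name, length(rc)),
        matched_seq = vapply(substring(seq, rc, rc + L - 1L),
                             reverseComplementPattern, character(1L),
                             USE.NAMES = FALSE),
        stringsAsFactors = FALSE)
      hits <- rbind(hits, rev_hits)
    }
  }
  if (nrow(hits)) {
    hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

#' Scan a collection of sequences
#'
#' Applies [scanSequence()] to every element of a named sequence set and
#' binds the per-element hit tables.
#'
#' @param seqs named character vector, list, or
#'   [Biostrings::DNAStringSet].
#' @inheritParams scanSequence
#' @return combined hit data.frame (see [scanSequence()]), ordered by
#'   element, then start, then strand.
#' @export
scanSet <- function(seqs, motif, strands = "forward") {
  seqs <- .asSeqVector(seqs)
  out <- lapply(names(seqs), function(id)
    scanSequence(seqs[[id]], motif, strands, element_id = id))
  out <- do.call(rbind, c(out, list(.emptyHits())))
  rownames(out) <- NULL
  out
}

#' Count motif occurrences in a sequence set
#'
#' Occurrence count (not per-element presence) of one motif, or of every
#' member of a [MotifFamily-class], over a sequence set.
#'
#' @inheritParams scanSet
#' @param motif an [IupacMotif-class], IUPAC string, or
#'   [MotifFamily-class].
#' @return for a single motif, an integer; for a family, a named integer
#'   vector over the member patterns (original first).
#' @export
countMotif <- function(seqs, motif, strands = "forward") {
  strands <- .normStrands(strands)
  seqs <- .asSeqVector(seqs)
  codes <- lapply(seqs, .seqCodes)
  patterns <- if (methods::is(motif, "MotifFamily")) motif@members
              else .asMotif(motif)@pattern
  counts <- vapply(patterns, function(p) {
    mats <- list(.allowedMatrix(p))
    if (strands == "both")
      mats <- c(mats, list(.allowedMatrix(reverseComplementPattern(p))))
    sum(vapply(codes, function(cd)
      sum(vapply(mats, function(m) length(.matchStarts(cd, m)), integer(1L))),
      integer(1L)))
  }, integer(1L))
  if (length(patterns) == 1L) unname(counts) else counts
}

# ---- shuffled-motif families ------------------------------------------------

.distinctPermutations <- function(chars) {
  # all distinct orderings of a letter multiset, lexicographic
  rec <- function(remaining) {
    if (!length(remaining)) return(list(character(0)))
    out <- list()
    for (ch in sort(unique(remaining))) {
      rest <- remaining[-match(ch, remaining)]
      for (tail in rec(rest)) out[[length(out) + 1L]] <- c(ch, tail)
    }
    out
  }
  vapply(rec(chars), paste, character(1L), collapse = "")
}

#' Build the shuffled-motif family null for a consensus motif
#'
#' The single-species null model compares a motif's occurrence count with
#' the counts of composition-matched shuffled variants. For motifs that
#' decompose as a 4-base fixed prefix, a block of `N`s, a 2-base fixed core
#' and an optional fixed suffix (e.g. `TGATNNAT`, `TGATNNATKR`), the family
#' is all distinct orderings of the prefix letter multiset crossed with the
#' core and its reversal, the `N` block and suffix held fixed in place —
#' 24 members for `TGATNNATKR`. Motifs outside that scheme fall back (under
#' `scheme = "auto"`) to a generic construction permuting the letter
#' multiset of *all* fixed-base positions while degenerate positions stay
#' fixed in place, flagged `construction = "generic"`.
#'
#' @param motif an [IupacMotif-class] or IUPAC string.
#' @param scheme `"auto"` (default), `"prefix_core"` (error if the motif
#'   does not decompose), or `"generic"`.
#' @return a [MotifFamily-class]; the original motif is the first member.
#' @examples
#' fam <- generateFamily("TGATNNATKR")
#' length(motifPatterns(fam))  # 24
#' @export
generateFamily <- function(motif, scheme = c("auto", "prefix_core", "generic")) {
  motif <- .asMotif(motif)
  scheme <- match.arg(scheme)
  chars <- strsplit(motif@pattern, "", fixed = TRUE)[[1L]]
  L <- length(chars)

  decompose <- function() {
    # [4 fixed][>=1 N][2 fixed][suffix, any IUPAC, held fixed]
    if (L < 7L) return(NULL)
    if (!all(chars[1:4] %in% c("A", "C", "G", "T"))) return(NULL)
    if (chars[5L] != "N") return(NULL)
    n_end <- 4L
    while (n_end < L && chars[n_end + 1L] == "N") n_end <- n_end + 1L
    if (n_end + 2L > L) return(NULL)
    core <- chars[(n_end + 1L):(n_end + 2L)]
    if (!all(core %in% c("A", "C", "G", "T"))) return(NULL)
    list(prefix = chars[1:4], n_block = chars[5:n_end], core = core,
         suffix = if (n_end + 2L < L) chars[(n_end + 3L):L] else character(0))
  }

  dec <- decompose()
  if (scheme == "prefix_core" && is.null(dec))
    stop("motif '", motif@pattern, "' does not decompose as ",
         "[4-base prefix][N block][2-base core][suffix]; ",
         "supply an explicit family or use scheme = 'generic'")

  if (scheme != "generic" && !is.null(dec)) {
    prefixes <- .distinctPermutations(dec$prefix)
    cores <- unique(c(paste(dec$core, collapse = ""),
                      paste(rev(dec$core), collapse = "")))
    nb <- paste(dec$n_block, collapse = "")
    sf <- paste(dec$suffix, collapse = "")
    members <- as.vector(t(outer(prefixes, cores,
                                 function(p, co) paste0(p, nb, co, sf))))
    members <- unique(members)
    construction <- "prefix_core"
  } else {
    fixed_idx <- which(chars %in% c("A", "C", "G", "T"))
    if (length(fixed_idx) < 2L)
      stop("motif '", motif@pattern,
           "' has fewer than two fixed positions; no family is defined")
    perms <- .distinctPermutations(chars[fixed_idx])
    members <- vapply(perms, function(p) {
      out <- chars
      out[fixed_idx] <- strsplit(p, "", fixed = TRUE)[[1L]]
      paste(out, collapse = "")
    }, character(1L), USE.NAMES = FALSE)
    members <- unique(members)
    construction <- "generic"
  }
  members <- c(motif@pattern, setdiff(members, motif@pattern))
  methods::new("MotifFamily", original = motif, members = members,
               construction = construction)
}

#' @rdname motif-accessors
#' @export
setMethod("motifPatterns", "MotifFamily", function(x) x@members)

#' @describeIn MotifFamily-class number of member motifs.
#' @param x a `MotifFamily`.
#' @export
setMethod("length", "MotifFamily", function(x) length(x@members))

setMethod("show", "MotifFamily", function(object) {
  cat(sprintf("MotifFamily for '%s' (%s construction): %d members\n",
              object@original@pattern, object@construction,
              length(object@members)))
  cat("  ", paste(utils::head(object@members, 8L), collapse = " "),
      if (length(object@members) > 8L) "..." else "", "\n")
})
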