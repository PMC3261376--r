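#' Read a FASTA file of element sequences
#'
#' Wraps [Biostrings::readDNAStringSet()]: ids are the first
#' whitespace-delimited token of each header, sequences are upper-cased,
#' and duplicate ids or an empty file are explicit errors.
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
readFasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (!length(ss)) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "))
  stats::setNames(toupper(as.character(ss)), ids)
}

#' Write element sequences as FASTA
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  seqs <- .asSeqVector(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read CNE multiple alignments
#'
#' Supported formats: `"fasta"` — aligned FASTA, either one alignment per
#' file or several alignments as blocks separated by one or more blank
#' lines (each block is a complete aligned-FASTA alignment); `"clustal"` —
#' ClustalW `.aln` (one alignment per file).
#'
#' @param path input file.
#' @param format `"fasta"` (default) or `"clustal"`.
#' @param ids alignment ids; default `basename(path)` plus a block index
#'   when the file holds several alignments.
#' @return list of [CneAlignment-class] objects.
#' @export
readAlignments <- function(path, format = c("fasta", "clustal"), ids = NULL) {
  format <- match.arg(format)
  if (format == "clustal") {
    aln <- .readClustal(path)
    if (is.null(ids)) ids <- basename(path)
    return(list(cneAlignment(ids[1L], aln)))
  }
  lines <- readLines(path)
  blank <- !nzchar(trimws(lines))
  block_id <- cumsum(blank & !c(TRUE, blank[-length(blank)]))
  block_id[blank] <- NA
  blocks <- split(lines[!blank], block_id[!blank])
  if (!length(blocks)) stop("no alignment blocks in ", path)
  if (is.null(ids)) {
    ids <- if (length(blocks) == 1L) basename(path)
           else paste0(basename(path), "_", seq_along(blocks))
  }
  stopifnot(length(ids) == length(blocks))
  mapply(function(blk, id) {
    cneAlignment(id, .parseFastaBlock(blk))
  }, blocks, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

.parseFastaBlock <- function(lines) {
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("aligned-FASTA block without headers")
  idx <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1L),
                 collapse = "")
  stats::setNames(toupper(seqs), ids)
}

.readClustal <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("CLUSTAL", lines[1L], ignore.case = TRUE))
    stop("not a ClustalW file (missing CLUSTAL header): ", path)
  body <- lines[-1L]
  acc <- list()
  for (ln in body) {
    if (!nzchar(trimws(ln))) next
    # conservation line: only spaces, '*', ':', '.'
    if (grepl("^[ *:.\t]+$", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) < 2L) next
    id <- parts[1L]
    acc[[id]] <- paste0(if (is.null(acc[[id]])) "" else acc[[id]], parts[2L])
  }
  if (length(acc) < 2L) stop("fewer than 2 sequences parsed from ", path)
  toupper(unlist(acc))
}

#' Write a motif hit table as TSV
#'
#' Columns: `element_id`, `start` (1-based inclusive), `end`, `strand`,
#' `motif_name`, `matched_seq` (conserved-hit tables keep their per-species
#' columns instead of `matched_seq`).
#'
#' @param hits data.frame from [scanSet()] or [conservedScan()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a hit table to BED6
#'
#' 0-based half-open coordinates, score 0, element id as chromosome/name
#' space.
#'
#' @param hits data.frame from [scanSequence()]/[scanSet()].
#' @return data.frame with BED6 columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
hitsToBed <- function(hits) {
  data.frame(chrom = hits$element_id,
             start = hits$start - 1L,   # 1-based inclusive -> 0-based half-open
             end = hits$end,
             name = hits$motif_name,
             score = 0L,
             strand = hits$strand,
             stringsAsFactors = FALSE)
}

.asGRanges <- function(x, what = "intervals") {
  if (methods::is(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop(what, " must be a GRanges or a data.frame with columns chrom, ",
         "start, end (0-based half-open)")
  if (any(x$end <= x$start)) stop("malformed ", what, ": end must exceed start")
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Overlap accounting between two interval collections
#'
#' Reports how many elements of each set overlap the other by at least one
#' base, the total number of shared bases (length of the intersection of
#' the two merged interval sets), and that total as a fraction of each
#' set's merged length.
#'
#' @param setA,setB [GenomicRanges::GRanges] objects, or data.frames with
#'   columns `chrom`, `start`, `end` in 0-based half-open coordinates.
#' @return an [OverlapReport-class].
#' @examples
#' a <- data.frame(chrom = "chr1", start = 0, end = 100)
#' b <- data.frame(chrom = "chr1", start = 50, end = 150)
#' overlapStats(a, b)
#' @export
overlapStats <- function(setA, setB) {
  a <- .asGRanges(setA, "setA")
  b <- .asGRanges(setB, "setB")
  ma <- GenomicRanges::reduce(a)
  mb <- GenomicRanges::reduce(b)
  shared <- sum(GenomicRanges::width(GenomicRanges::intersect(ma, mb)))
  wa <- sum(GenomicRanges::width(ma))
  wb <- sum(GenomicRanges::width(mb))
  methods::new("OverlapReport",
               nAOverlapping = sum(IRanges::overlapsAny(a, b)),
               nBOverlapping = sum(IRanges::overlapsAny(b, a)),
               sharedBases = as.integer(shared),
               fractionOfA = if (wa > 0) shared / wa else 0,
               fractionOfB = if (wb > 0) shared / wb else 0)
}

setMethod("show", "OverlapReport", function(object) {
  cat(sprintf(
    "OverlapReport: %d elements of A and %d of B overlap;\n  %d shared bases (%.1f%% of A, %.1f%% of B, merged totals)\n",
    object@nAOverlapping, object@nBOverlapping, object@sharedBases,
    100 * object@fractionOfA, 100 * object@fractionOfB))
})

#' Published motif-family occurrence counts bundled with the package
#'
#' Occurrence counts of the stringent Pbx-Hox `TGATNNATKR` motif and its 23
#' shuffled family variants in seven published conserved-element
#' collections (CONDOR CNEs, human/shark CNEs, the VISTA Enhancer Browser
#' set and its hindbrain/branchial-arch/cranial-nerve annotated subsets,
#' and the zebrafish cneBrowser set with its hindbrain-positive subset).
#' These printed counts are inputs for [familyEnrichment()] worked
#' examples and regression checks.
#'
#' @return data.frame, first column `motif` (original motif first), one
#'   numeric column per dataset.
#' @export
krFamilyCounts <- function() {
  path <- system.file("extdata", "kr_family_counts.tsv",
                      package = "cneMotifs", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
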