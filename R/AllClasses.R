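#' @import methods
NULL

#' Degenerate IUPAC DNA motif
#'
#' A consensus binding-site motif written in the 15-letter IUPAC nucleotide
#' alphabet, e.g. the Pbx-Hox core `TGATNNAT`, its stringent extension
#' `TGATNNATKR` (K = G/T, R = A/G) or the Meis site `TGACAR`. Matching is
#' exact set membership per position; there is no scoring or threshold.
#'
#' @slot pattern upper-case IUPAC string.
#' @slot name free-text label (defaults to the pattern).
#' @seealso [iupacMotif()], [scanSequence()], [generateFamily()]
#' @export
setClass("IupacMotif",
         representation(pattern = "character", name = "character"))

setValidity("IupacMotif", function(object) {
  if (length(object@pattern) != 1L || !nzchar(object@pattern))
    return("'pattern' must be a single non-empty string")
  chars <- strsplit(object@pattern, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% .IUPAC_ALPHABET)
  if (length(bad))
    return(sprintf("invalid IUPAC code '%s' at position %d",
                   chars[bad[1L]], bad[1L]))
  if (length(object@name) != 1L)
    return("'name' must be a single string")
  TRUE
})

#' Family of shuffled motif variants
#'
#' The single-species null model for consensus-motif counting: a set of
#' variants of one motif obtained by permuting its fixed-base letters while
#' holding the degenerate positions fixed in place. Occurrence counts of the
#' family members in the same sequence set provide the empirical null for
#' the original motif's count.
#'
#' @slot original the [IupacMotif-class] the family was built from.
#' @slot members character vector of member patterns, original first,
#'   pairwise distinct.
#' @slot construction `"prefix_core"` (prefix-permutation x core/reversed
#'   core scheme) or `"generic"` (all fixed positions permuted jointly).
#' @seealso [generateFamily()], [familyEnrichment()]
#' @export
setClass("MotifFamily",
         representation(original = "IupacMotif", members = "character",
                        construction = "character"))

setValidity("MotifFamily", function(object) {
  if (length(object@members) < 1L) return("family has no members")
  if (anyDuplicated(object@members)) return("members must be distinct")
  if (object@members[1L] != object@original@pattern)
    return("first member must be the original pattern")
  if (length(unique(nchar(object@members))) != 1L)
    return("members must all have the motif's length")
  TRUE
})

#' Multi-species CNE alignment
#'
#' A gapped multiple sequence alignment of homologous conserved non-coding
#' elements, one row per species, all rows the same number of columns.
#'
#' @slot id alignment identifier.
#' @slot species species labels, parallel to the rows.
#' @slot rows upper-case gapped sequences over `A,C,G,T,N,-` (other IUPAC
#'   letters are tolerated but never match a motif).
#' @seealso [cneAlignment()], [conservedScan()], [shuffleColumns()]
#' @export
setClass("CneAlignment",
         representation(id = "character", species = "character",
                        rows = "character"))

setValidity("CneAlignment", function(object) {
  if (length(object@rows) < 2L) return("an alignment needs >= 2 rows")
  if (length(object@species) != length(object@rows))
    return("'species' and 'rows' lengths differ")
  if (length(unique(nchar(object@rows))) != 1L)
    return("rows must all have the same number of columns")
  if (nchar(object@rows[1L]) < 1L) return("alignment has zero columns")
  ungapped <- gsub("-", "", object@rows, fixed = TRUE)
  if (any(!nzchar(ungapped)))
    return("every row must contain at least one non-gap character")
  TRUE
})

#' Column-shuffled alignment null model
#'
#' Result of comparing the observed whole-dataset count of conserved motif
#' hits against replicate datasets in which every alignment had its columns
#' permuted (per-column vertical content preserved, positional structure
#' destroyed).
#'
#' @slot motifName motif label.
#' @slot strands `"forward"` or `"both"`.
#' @slot nReplicates number of shuffled replicates.
#' @slot seed base seed; replicate r uses `seed + r`.
#' @slot counts integer conserved-hit totals, one per replicate.
#' @slot observed conserved-hit total in the unshuffled data.
#' @slot foldEnrichment `observed / mean(counts)` (`Inf` when the null mean
#'   is zero).
#' @seealso [alignmentNull()]
#' @export
setClass("ShuffledAlignmentNull",
         representation(motifName = "character", strands = "character",
                        nReplicates = "integer", seed = "integer",
                        counts = "integer", observed = "integer",
                        foldEnrichment = "numeric"))

setValidity("ShuffledAlignmentNull", function(object) {
  if (length(object@counts) != object@nReplicates)
    return("'counts' length must equal nReplicates")
  if (any(object@counts < 0L)) return("null counts must be >= 0")
  TRUE
})

#' Motif enrichment against an empirical null
#'
#' Observed occurrence count of a motif in a dataset together with the null
#' count collection it is compared against, the resulting z-score and the
#' one-sided (upper tail) normal p-value.
#'
#' For `nullKind = "motif_family"` the mean and standard deviation are taken
#' over the counts of *all* family members including the original motif, and
#' the standard deviation uses the sample (n-1) denominator.
#'
#' @slot motifName,datasetName labels.
#' @slot observed observed count of the original motif.
#' @slot nullCounts the count collection the mean/SD are computed over.
#' @slot mean,sd summary of `nullCounts`.
#' @slot z `(observed - mean)/sd`; `NA` when `sd == 0`.
#' @slot p one-sided upper-tail normal p-value of `z`.
#' @slot nullKind `"motif_family"` or `"markov0_shuffle"`.
#' @slot strands strand convention that produced the counts.
#' @slot note diagnostic string (e.g. degenerate SD).
#' @seealso [familyEnrichment()], [isSignificant()]
#' @export
setClass("EnrichmentResult",
         representation(motifName = "character", datasetName = "character",
                        observed = "numeric", nullCounts = "numeric",
                        mean = "numeric", sd = "numeric",
                        z = "numeric", p = "numeric",
                        nullKind = "character", strands = "character",
                        note = "character"))

setValidity("EnrichmentResult", function(object) {
  if (object@sd < 0) return("sd must be >= 0")
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    return("p must lie in [0, 1]")
  TRUE
})

#' Motif-density comparison between two element classes
#'
#' One-degree-of-freedom chi-square test of whether motif occurrences are
#' distributed between two sequence classes in proportion to their total
#' lengths (no continuity correction).
#'
#' @slot countA,countB observed counts.
#' @slot lengthA,lengthB total sequence lengths in bp.
#' @slot chiSquare test statistic; @slot df always 1; @slot p p-value.
#' @slot rateRatio `(countA/lengthA) / (countB/lengthB)`.
#' @seealso [densityChiSquare()]
#' @export
setClass("DensityComparison",
         representation(countA = "numeric", countB = "numeric",
                        lengthA = "numeric", lengthB = "numeric",
                        chiSquare = "numeric", df = "integer",
                        p = "numeric", rateRatio = "numeric"))

#' Per-locus motif enrichment against a Markov-0 null
#'
#' Motif count over all CNEs associated with one gene locus, compared with
#' counts in replicate control sets in which every CNE is regenerated i.i.d.
#' from the global base composition of the full CNE collection.
#'
#' @slot locus gene/locus label.
#' @slot motifName,strands motif label and strand convention.
#' @slot observed total motif count over the locus CNEs.
#' @slot totalBp summed CNE length; @slot hitsPerKb `observed/(totalBp/1000)`.
#' @slot controlMean,controlSd sample mean and (n-1) SD of control counts.
#' @slot z,p z-score and one-sided upper-tail normal p-value.
#' @slot nSets number of control sets; @slot seed RNG seed used.
#' @seealso [locusEnrichment()]
#' @export
setClass("LocusEnrichment",
         representation(locus = "character", motifName = "character",
                        strands = "character", observed = "integer",
                        totalBp = "integer", hitsPerKb = "numeric",
                        controlMean = "numeric", controlSd = "numeric",
                        z = "numeric", p = "numeric",
                        nSets = "integer", seed = "integer"))

#' Position frequency matrix over aligned motif hit windows
#'
#' Per-position base counts over a set of motif hits, each extended by a
#' fixed number of downstream (3') flanking bases in motif orientation —
#' the input for sequence-logo rendering of, e.g., the KR extension of the
#' Pbx-Hox core.
#'
#' @slot counts 4 x P integer matrix, rows A, C, G, T.
#' @slot nSites number of hit windows tabulated.
#' @slot nDropped hits discarded because the flank ran off the element end.
#' @slot source descriptor (motif, dataset, flank size).
#' @seealso [buildPfm()], [pfmToLogoTable()]
#' @export
setClass("PositionFrequencyMatrix",
         representation(counts = "matrix", nSites = "integer",
                        nDropped = "integer", source = "character"))

setValidity("PositionFrequencyMatrix", function(object) {
  if (!identical(rownames(object@counts), c("A", "C", "G", "T")))
    return("counts rows must be A, C, G, T")
  if (any(object@counts < 0)) return("counts must be >= 0")
  TRUE
})

#' Interval-overlap accounting between two element collections
#'
#' @slot nAOverlapping,nBOverlapping number of elements of each set with at
#'   least one base overlapping the other set.
#' @slot sharedBases total length of the intersection of the two merged
#'   interval sets.
#' @slot fractionOfA,fractionOfB `sharedBases` relative to each set's
#'   merged total length.
#' @seealso [overlapStats()]
#' @export
setClass("OverlapReport",
         representation(nAOverlapping = "integer", nBOverlapping = "integer",
                        sharedBases = "integer", fractionOfA = "numeric",
                        fractionOfB = "numeric"))
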