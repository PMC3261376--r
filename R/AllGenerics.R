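#' Accessor generics for result objects
#'
#' Small accessor family shared by the null-model result classes:
#' `observedCount()` returns the observed motif count, `nullCounts()` the
#' replicate/null count collection, `zScore()` and `pValue()` the test
#' statistic and p-value, `foldEnrichment()` the observed/null-mean ratio,
#' and `isSignificant()` applies the reporting threshold (results with
#' p > alpha are flagged not significant, mirroring an "N/S" table cell).
#'
#' @param x a result object ([EnrichmentResult-class],
#'   [ShuffledAlignmentNull-class], [LocusEnrichment-class] or
#'   [DensityComparison-class], where applicable).
#' @param alpha significance threshold for `isSignificant()` (default 0.05).
#' @return a numeric scalar/vector, or a logical for `isSignificant()`
#'   (`FALSE` when the statistic is undefined).
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
setGeneric("observedCount", function(x) standardGeneric("observedCount"))

#' @rdname result-accessors
#' @export
setGeneric("nullCounts", function(x) standardGeneric("nullCounts"))

#' @rdname result-accessors
#' @export
setGeneric("zScore", function(x) standardGeneric("zScore"))

#' @rdname result-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname result-accessors
#' @export
setGeneric("foldEnrichment", function(x) standardGeneric("foldEnrichment"))

#' @rdname result-accessors
#' @export
setGeneric("isSignificant", function(x, alpha = 0.05)
  standardGeneric("isSignificant"))

#' Motif accessors
#'
#' `motifPattern()` returns the IUPAC string, `motifName()` the label, and
#' `motifSets()` the per-position allowed-base sets (a list of character
#' vectors, e.g. `N` expands to `c("A","C","G","T")`, `K` to `c("G","T")`).
#' `motifPatterns()` returns all member patterns of a [MotifFamily-class].
#'
#' @param x an [IupacMotif-class] (or [MotifFamily-class] for
#'   `motifPatterns()`).
#' @return character scalar, list, or character vector respectively.
#' @name motif-accessors
NULL

#' @rdname motif-accessors
#' @export
setGeneric("motifPattern", function(x) standardGeneric("motifPattern"))

#' @rdname motif-accessors
#' @export
setGeneric("motifName", function(x) standardGeneric("motifName"))

#' @rdname motif-accessors
#' @export
setGeneric("motifSets", function(x) standardGeneric("motifSets"))

#' @rdname motif-accessors
#' @export
setGeneric("motifPatterns", function(x) standardGeneric("motifPatterns"))

#' Alignment accessors
#'
#' `alignmentId()` returns the identifier, `speciesNames()` the species
#' labels, `alignmentRows()` the gapped row strings (named by species) and
#' `alignmentWidth()` the number of alignment columns.
#'
#' @param x a [CneAlignment-class].
#' @return character scalar/vector or integer.
#' @name alignment-accessors
NULL

#' @rdname alignment-accessors
#' @export
setGeneric("alignmentId", function(x) standardGeneric("alignmentId"))

#' @rdname alignment-accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname alignment-accessors
#' @export
setGeneric("alignmentRows", function(x) standardGeneric("alignmentRows"))

#' @rdname alignment-accessors
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))
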