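#' Run the conserved-motif enrichment pipeline end to end
#'
#' Chains the stages on one configuration: load (or synthesize) a sequence
#' set and/or alignment set, scan for the motif, build the shuffled-motif
#' family null and its enrichment z-score, run the column-shuffled
#' alignment null for conserved hits, tabulate the position frequency
#' matrix, and write all result tables plus a machine-readable run
#' manifest. Reruns with the same configuration reproduce all outputs
#' byte-identically (no timestamps are written).
#'
#' @param config named list (or path to a YAML file with the same keys):
#'   \describe{
#'     \item{motif}{IUPAC pattern to scan for (required).}
#'     \item{strands}{`"forward"` (default) or `"both"`.}
#'     \item{seed}{integer seed for all resampling stages (default 1).}
#'     \item{datasetName}{label for result records.}
#'     \item{sequences}{list with either `fasta = <path>` or
#'       `synthetic = <list of generateCneSet() arguments>`.}
#'     \item{alignments}{optional list with `fasta`/`clustal = <path>` or
#'       `synthetic = <list of generateAlignmentSet() arguments>`.}
#'     \item{nReplicates}{alignment-null replicates (default 1000).}
#'     \item{familyScheme}{passed to [generateFamily()] (default "auto").}
#'     \item{pfmFlank}{3' flank for the PFM (default 2).}
#'   }
#' @param outDir output directory (created if needed); `NULL` skips all
#'   file output.
#' @return (invisibly) list with elements `hits`, `familyCounts`,
#'   `familyEnrichment`, `pfm`, `conservedHits`, `alignmentNull`,
#'   `manifest` (entries `NULL` when the corresponding stage was not
#'   configured).
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$motif))
  motif <- .asMotif(config$motif)
  strands <- .normStrands(config$strands %||% "forward")
  seed <- as.integer(config$seed %||% 1L)
  dataset <- config$datasetName %||% "dataset"
  consumed <- character(0)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  bundle <- list(hits = NULL, familyCounts = NULL, familyEnrichment = NULL,
                 pfm = NULL, conservedHits = NULL, alignmentNull = NULL,
                 manifest = NULL)

  seqs <- NULL
  if (!is.null(config$sequences)) {
    seqs <- stage("load_sequences", {
      sq <- config$sequences
      if (!is.null(sq$fasta)) {
        consumed <<- c(consumed, sq$fasta)
        readFasta(sq$fasta)
      } else if (!is.null(sq$synthetic)) {
        args <- sq$synthetic
        if (is.null(args$seed)) args$seed <- seed
        do.call(generateCneSet, args)$seqs
      } else stop("sequences needs 'fasta' or 'synthetic'")
    })
    bundle$hits <- stage("scan", scanSet(seqs, motif, strands))
    fam <- stage("family", generateFamily(motif,
                                          config$familyScheme %||% "auto"))
    counts <- stage("family_counts", countMotif(seqs, fam, strands))
    bundle$familyCounts <- counts
    bundle$familyEnrichment <- stage("family_enrichment",
      familyEnrichment(counts, datasetName = dataset,
                       motifName = motif@name, strands = strands))
    if (nrow(bundle$hits)) {
      bundle$pfm <- stage("pfm",
        buildPfm(bundle$hits, seqs, config$pfmFlank %||% 2L))
    }
  }

  alns <- NULL
  if (!is.null(config$alignments)) {
    alns <- stage("load_alignments", {
      al <- config$alignments
      if (!is.null(al$fasta)) {
        consumed <<- c(consumed, al$fasta)
        readAlignments(al$fasta, "fasta")
      } else if (!is.null(al$clustal)) {
        consumed <<- c(consumed, al$clustal)
        readAlignments(al$clustal, "clustal")
      } else if (!is.null(al$synthetic)) {
        args <- al$synthetic
        if (is.null(args$seed)) args$seed <- seed
        do.call(generateAlignmentSet, args)$alignments
      } else stop("alignments needs 'fasta', 'clustal' or 'synthetic'")
    })
    bundle$conservedHits <- stage("conserved_scan",
      do.call(rbind, lapply(alns, conservedScan, motif = motif,
                            strands = strands)))
    bundle$alignmentNull <- stage("alignment_null",
      alignmentNull(alns, motif, config$nReplicates %||% 1000L,
                    seed = seed, strands = strands))
  }

  bundle$manifest <- list(
    package = "cneMotifs",
    version = as.character(utils::packageVersion("cneMotifs")),
    parameters = list(motif = motif@pattern, motif_name = motif@name,
                      strands = strands, seed = seed,
                      dataset = dataset,
                      nReplicates = as.integer(config$nReplicates %||% 1000L),
                      pfmFlank = as.integer(config$pfmFlank %||% 2L)),
    inputs = if (length(consumed)) {
      data.frame(path = consumed, md5 = unname(tools::md5sum(consumed)),
                 stringsAsFactors = FALSE)
    } else NULL)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(outDir, f)
    if (!is.null(bundle$hits)) writeHits(bundle$hits, out("hits.tsv"))
    if (!is.null(bundle$familyCounts)) {
      utils::write.table(
        data.frame(motif = names(bundle$familyCounts),
                   count = unname(bundle$familyCounts)),
        out("family_counts.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    if (!is.null(bundle$familyEnrichment)) {
      jsonlite::write_json(
        as.list(as.data.frame(bundle$familyEnrichment)),
        out("family_enrichment.json"), auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(bundle$pfm)) {
      writePfm(bundle$pfm, out("pfm.tsv"))
      writeMeme(bundle$pfm, out("pfm_meme.txt"), name = motif@name)
    }
    if (!is.null(bundle$conservedHits))
      writeHits(bundle$conservedHits, out("conserved_hits.tsv"))
    if (!is.null(bundle$alignmentNull)) {
      an <- bundle$alignmentNull
      jsonlite::write_json(
        list(motif = an@motifName, strands = an@strands,
             observed = an@observed, n_replicates = an@nReplicates,
             null_mean = mean(an@counts), null_sd = stats::sd(an@counts),
             fold_enrichment = an@foldEnrichment, seed = an@seed),
        out("alignment_null.json"), auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(bundle$manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
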