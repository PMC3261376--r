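# Synthetic CNE sets and multi-species alignments with planted,
# ground-truth motif instances. The generator exists to make every pipeline
# stage testable end to end: background composition, element lengths and
# planted-motif densities are controllable, and every planted instance is
# recorded so scans can be checked against truth exactly.

.BASES <- c("A", "C", "G", "T")

# sample one concrete realization of a degenerate motif, uniform per position
.realizeMotif <- function(motif) {
  vapply(motifSets(motif), function(s) s[sample.int(length(s), 1L)],
         character(1L), USE.NAMES = FALSE)
}

# Generate one element as a character vector with nPlant non-overlapping
# planted instances; optionally scrub accidental background matches.
.generateElement <- function(len, probs, motif, nPlant, scrub, strands) {
  chars <- sample(.BASES, len, replace = TRUE, prob = probs)
  truth <- NULL
  if (is.null(motif) || nPlant == 0L) {
    if (!is.null(motif) && scrub)
      chars <- .scrubElement(chars, probs, motif, truth, strands)$chars
    return(list(chars = chars, truth = truth))
  }
  L <- length(motif)
  if (len < L) {
    warning("element of length ", len, " too short for a ", L,
            " bp motif; planted count forced to 0")
    return(list(chars = chars, truth = NULL))
  }
  occupied <- logical(len)
  starts <- integer(0)
  for (i in seq_len(nPlant)) {
    placed <- FALSE
    for (attempt in seq_len(100L)) {
      s <- sample.int(len - L + 1L, 1L)
      if (!any(occupied[s:(s + L - 1L)])) {
        occupied[s:(s + L - 1L)] <- TRUE
        starts <- c(starts, s)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      warning("could not place a motif instance after 100 attempts; skipped")
  }
  starts <- sort(starts)
  for (s in starts) chars[s:(s + L - 1L)] <- .realizeMotif(motif)
  if (length(starts)) {
    truth <- data.frame(start = starts, end = starts + L - 1L,
                        strand = "+", stringsAsFactors = FALSE)
  }
  if (scrub) {
    res <- .scrubElement(chars, probs, motif, truth, strands)
    chars <- res$chars
    truth <- res$truth
  }
  if (!is.null(truth))
    truth$matched_seq <- vapply(truth$start, function(s)
      paste(chars[s:(s + L - 1L)], collapse = ""), character(1L))
  list(chars = chars, truth = truth)
}

# Redraw background windows that accidentally match the motif, leaving
# planted windows intact; if a spurious hit lies entirely inside planted
# windows, the overlapped planted realization is resampled instead.
.scrubElement <- function(chars, probs, motif, truth, strands,
                          max_iter = 50L) {
  L <- length(motif)
  allowed <- list("+" = .allowedMatrix(motif@pattern))
  if (strands == "both")
    allowed[["-"]] <- .allowedMatrix(reverseComplementPattern(motif@pattern))
  planted_mask <- logical(length(chars))
  if (!is.null(truth)) {
    for (i in seq_len(nrow(truth)))
      planted_mask[truth$start[i]:truth$end[i]] <- TRUE
  }
  codes_of <- function(ch) .seqCodes(paste(ch, collapse = ""))
  for (iter in seq_len(max_iter)) {
    codes <- codes_of(chars)
    spurious <- NULL
    for (strand in names(allowed)) {
      s <- .matchStarts(codes, allowed[[strand]])
      if (!is.null(truth) && strand == "+")
        s <- setdiff(s, truth$start)
      if (length(s))
        spurious <- rbind(spurious, data.frame(start = s, strand = strand))
    }
    if (is.null(spurious) || !nrow(spurious)) return(list(chars = chars, truth = truth))
    for (i in seq_len(nrow(spurious))) {
      win <- spurious$start[i]:(spurious$start[i] + L - 1L)
      redraw <- win[!planted_mask[win]]
      if (length(redraw)) {
        chars[redraw] <- sample(.BASES, length(redraw), replace = TRUE,
                                prob = probs)
      } else if (!is.null(truth)) {
        # spurious window entirely inside planted material: resample the
        # overlapped planted realizations
        hit <- which(truth$start <= max(win) & truth$end >= min(win))
        for (j in hit)
          chars[truth$start[j]:truth$end[j]] <- .realizeMotif(motif)
      }
    }
  }
  warning("scrubbing did not converge after ", max_iter, " iterations")
  list(chars = chars, truth = truth)
}

#' Generate a synthetic CNE set with planted motif instances
#'
#' Elements have i.i.d. background drawn from `baseProbs` (AT-biased by
#' default, as vertebrate CNEs are) and normally distributed lengths
#' (truncated below at the motif length), emulating CNE collections with a
#' ~116 bp average element. Each element receives a Poisson-distributed
#' number of planted motif instances at non-overlapping uniform positions,
#' each a uniform draw from the motif's concrete realizations; positions
#' are recorded as ground truth. With `scrub = TRUE`, background windows
#' that match the motif by chance are redrawn until the set contains
#' exactly the planted instances (under the given strand convention).
#'
#' @param nElements number of elements (>= 1).
#' @param lengthMean,lengthSd element length distribution in bp
#'   (defaults 116 and 30).
#' @param baseProbs background probabilities for A, C, G, T
#'   (default `c(0.3, 0.2, 0.2, 0.3)`).
#' @param plantedMotif [IupacMotif-class], IUPAC string, or `NULL`.
#' @param plantedDensity expected planted instances per element.
#' @param scrub redraw accidental background matches (default `TRUE`;
#'   ignored when `plantedMotif` is `NULL`).
#' @param strands strand convention used for scrubbing.
#' @param seed optional integer seed.
#' @param prefix element id prefix.
#' @return list with `seqs` (named character vector), `truth` (hit-table
#'   data.frame with a `planted` flag) and `config` (the parameters used).
#' @examples
#' set <- generateCneSet(10, plantedMotif = "TGATNNATKR",
#'                       plantedDensity = 1, seed = 7)
#' nrow(set$truth) == nrow(scanSet(set$seqs, "TGATNNATKR"))
#' @export
generateCneSet <- function(nElements, lengthMean = 116, lengthSd = 30,
                           baseProbs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                           plantedMotif = NULL, plantedDensity = 0,
                           scrub = TRUE, strands = "forward", seed = NULL,
                           prefix = "cne") {
  stopifnot(nElements >= 1, plantedDensity >= 0)
  probs <- .checkProbs(baseProbs)
  strands <- .normStrands(strands)
  motif <- if (is.null(plantedMotif)) NULL else .asMotif(plantedMotif)
  if (!is.null(seed)) set.seed(seed)
  min_len <- 1L  # elements shorter than the motif simply carry no plants

  seqs <- character(nElements)
  ids <- paste0(prefix, "_", seq_len(nElements))
  truth_rows <- vector("list", nElements)
  for (i in seq_len(nElements)) {
    len <- max(min_len, as.integer(round(stats::rnorm(1, lengthMean, lengthSd))))
    n_plant <- if (is.null(motif)) 0L else stats::rpois(1L, plantedDensity)
    el <- .generateElement(len, probs, motif, n_plant,
                           scrub = scrub && !is.null(motif), strands)
    seqs[i] <- paste(el$chars, collapse = "")
    if (!is.null(el$truth)) {
      el$truth <- cbind(data.frame(element_id = ids[i],
                                   stringsAsFactors = FALSE),
                        el$truth)
      truth_rows[[i]] <- el$truth
    }
  }
  names(seqs) <- ids
  truth <- do.call(rbind, truth_rows)
  if (is.null(truth)) {
    truth <- .emptyHits()
    truth$planted <- logical(0)
  } else {
    truth$motif_name <- motif@name
    truth$planted <- TRUE
    truth <- truth[, c("element_id", "start", "end", "strand",
                       "motif_name", "matched_seq", "planted")]
  }
  list(seqs = seqs, truth = truth,
       config = list(nElements = nElements, lengthMean = lengthMean,
                     lengthSd = lengthSd, baseProbs = probs,
                     plantedMotif = if (is.null(motif)) NULL else motif@pattern,
                     plantedDensity = plantedDensity, scrub = scrub,
                     strands = strands, seed = seed))
}

#' Generate synthetic multi-species CNE alignments with conserved planted motifs
#'
#' Each alignment derives its species rows from a common ancestor element
#' (generated as in [generateCneSet()]): outside planted windows, each row
#' receives i.i.d. substitutions at `substitutionRate` per position, and
#' gap columns are introduced at `gapRate` per column by deleting the base
#' of one randomly chosen row. Planted windows are never substituted or
#' gapped — the generator's idealization of the premise that functional
#' binding sites are the conserved blocks within otherwise diverged CNEs —
#' so every planted instance is a gap-free, perfectly conserved motif at
#' identical aligned positions.
#'
#' @param nAlignments number of alignments.
#' @param nSpecies rows per alignment (>= 2, default 4).
#' @param species optional species labels (default `sp1..spN`).
#' @param substitutionRate per-branch per-site substitution probability
#'   outside planted windows, in `[0, 1)`.
#' @param gapRate per-column probability of a single-row gap, in `[0, 1)`.
#' @inheritParams generateCneSet
#' @return list with `alignments` (list of [CneAlignment-class]), `truth`
#'   (conserved-hit table: `alignment_id`, `column_start`, `column_end`,
#'   `strand`, `motif_name`, `matched_seq`, `planted`) and `config`.
#' @export
generateAlignmentSet <- function(nAlignments, nSpecies = 4L, species = NULL,
                                 lengthMean = 116, lengthSd = 30,
                                 baseProbs = c(A = 0.3, C = 0.2, G = 0.2,
                                               T = 0.3),
                                 plantedMotif = NULL, plantedDensity = 0,
                                 substitutionRate = 0.1, gapRate = 0.02,
                                 scrub = TRUE, strands = "forward",
                                 seed = NULL, prefix = "aln") {
  stopifnot(nAlignments >= 1, nSpecies >= 2,
            substitutionRate >= 0, substitutionRate < 1,
            gapRate >= 0, gapRate < 1)
  probs <- .checkProbs(baseProbs)
  strands <- .normStrands(strands)
  motif <- if (is.null(plantedMotif)) NULL else .asMotif(plantedMotif)
  if (is.null(species)) species <- paste0("sp", seq_len(nSpecies))
  stopifnot(length(species) == nSpecies)
  if (!is.null(seed)) set.seed(seed)
  min_len <- max(2L, if (is.null(motif)) 2L else length(motif))

  alignments <- vector("list", nAlignments)
  truth_rows <- vector("list", nAlignments)
  for (i in seq_len(nAlignments)) {
    id <- paste0(prefix, "_", i)
    len <- max(min_len, as.integer(round(stats::rnorm(1, lengthMean, lengthSd))))
    n_plant <- if (is.null(motif)) 0L else stats::rpois(1L, plantedDensity)
    anc <- .generateElement(len, probs, motif, n_plant,
                            scrub = scrub && !is.null(motif), strands)
    planted_mask <- logical(len)
    if (!is.null(anc$truth)) {
      for (j in seq_len(nrow(anc$truth)))
        planted_mask[anc$truth$start[j]:anc$truth$end[j]] <- TRUE
    }
    free <- which(!planted_mask)
    rows <- matrix(rep(anc$chars, nSpecies), nrow = nSpecies, byrow = TRUE)
    if (substitutionRate > 0 && length(free)) {
      for (r in seq_len(nSpecies)) {
        mut <- free[stats::runif(length(free)) < substitutionRate]
        if (length(mut)) {
          # substitute with one of the three other bases, uniformly
          cur <- match(rows[r, mut], .BASES)
          shift <- sample.int(3L, length(mut), replace = TRUE)
          rows[r, mut] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
        }
      }
    }
    if (gapRate > 0 && length(free)) {
      gap_cols <- free[stats::runif(length(free)) < gapRate]
      if (length(gap_cols)) {
        gap_row <- sample.int(nSpecies, length(gap_cols), replace = TRUE)
        rows[cbind(gap_row, gap_cols)] <- "-"
      }
    }
    row_strings <- apply(rows, 1L, paste, collapse = "")
    alignments[[i]] <- cneAlignment(id, stats::setNames(row_strings, species))
    if (!is.null(anc$truth)) {
      truth_rows[[i]] <- data.frame(
        alignment_id = id, column_start = anc$truth$start,
        column_end = anc$truth$end, strand = anc$truth$strand,
        motif_name = motif@name, matched_seq = anc$truth$matched_seq,
        planted = TRUE, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_rows)
  if (is.null(truth)) {
    truth <- data.frame(alignment_id = character(0),
                        column_start = integer(0), column_end = integer(0),
                        strand = character(0), motif_name = character(0),
                        matched_seq = character(0), planted = logical(0),
                        stringsAsFactors = FALSE)
  }
  list(alignments = alignments, truth = truth,
       config = list(nAlignments = nAlignments, nSpecies = nSpecies,
                     species = species, lengthMean = lengthMean,
                     lengthSd = lengthSd, baseProbs = probs,
                     plantedMotif = if (is.null(motif)) NULL else motif@pattern,
                     plantedDensity = plantedDensity,
                     substitutionRate = substitutionRate, gapRate = gapRate,
                     scrub = scrub, strands = strands, seed = seed))
}
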