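# Integer-code machinery shared by the scanners. Sequences are mapped to
# codes 1..4 (A,C,G,T); anything else (gaps, N in the *subject*, IUPAC
# ambiguity letters) maps to 0 and can never satisfy a motif position.

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_ALPHABET <- names(.IUPAC_SETS)

# code lookup indexed by raw byte value + 1
.CODE_TABLE <- local({
  tab <- integer(256L)
  tab[utf8ToInt("A") + 1L] <- 1L
  tab[utf8ToInt("C") + 1L] <- 2L
  tab[utf8ToInt("G") + 1L] <- 3L
  tab[utf8ToInt("T") + 1L] <- 4L
  tab
})

.seqCodes <- function(x) {
  .CODE_TABLE[utf8ToInt(toupper(x)) + 1L]
}

# L x 5 logical matrix: row k / column c+1 is TRUE iff subject code c
# (0 = non-ACGT, 1..4 = A,C,G,T) satisfies motif position k.
.allowedMatrix <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  m <- matrix(FALSE, nrow = length(chars), ncol = 5L)
  base_code <- c(A = 2L, C = 3L, G = 4L, T = 5L)  # column index
  for (k in seq_along(chars)) {
    m[k, base_code[.IUPAC_SETS[[chars[k]]]]] <- TRUE
  }
  m
}

# Start offsets (1-based) of windows of `codes` satisfying `allowed`.
.matchStarts <- function(codes, allowed) {
  L <- nrow(allowed)
  n <- length(codes)
  if (n < L) return(integer(0L))
  v <- allowed[1L, codes[1:(n - L + 1L)] + 1L]
  if (L > 1L) {
    for (k in 2:L) {
      v <- v & allowed[k, codes[k:(n - L + k)] + 1L]
    }
  }
  which(v)
}

.validateIupac <- function(pattern, what = "pattern") {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% .IUPAC_ALPHABET)
  if (length(bad)) {
    stop(sprintf("invalid IUPAC code '%s' in %s '%s' at position %d",
                 chars[bad[1L]], what, pattern, bad[1L]), call. = FALSE)
  }
  invisible(pattern)
}

#' Reverse complement of an IUPAC pattern string
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()] so degenerate consensus patterns can be
#' flipped without manual `DNAString` juggling. Degenerate codes are
#' complemented by set (K <-> M, R <-> Y, N <-> N); the operation is an
#' involution.
#'
#' @param x single character string over the IUPAC alphabet.
#' @return the reverse-complemented pattern, upper case.
#' @examples
#' reverseComplementPattern("TGATNNATKR")  # "YMATNNATCA"
#' @export
reverseComplementPattern <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  if (!nzchar(x)) return(x)
  .validateIupac(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# coerce various sequence containers to a named character vector
.asSeqVector <- function(seqs, default_prefix = "seq") {
  if (methods::is(seqs, "XStringSet")) {
    out <- as.character(seqs)
  } else if (methods::is(seqs, "XString")) {
    out <- as.character(seqs)
  } else if (is.list(seqs)) {
    out <- unlist(seqs, use.names = TRUE)
  } else {
    out <- seqs
  }
  stopifnot(is.character(out))
  out <- toupper(out)
  if (!length(out)) return(stats::setNames(character(0), character(0)))
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    names(out) <- paste0(default_prefix, seq_along(out))
  }
  out
}

.emptyHits <- function() {
  data.frame(element_id = character(0), start = integer(0),
             end = integer(0), strand = character(0),
             motif_name = character(0), matched_seq = character(0),
             stringsAsFactors = FALSE)
}
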