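# Independent oracles and random-case generators. These deliberately avoid
# the package's scanning machinery: the IUPAC map is written out again and
# matching is a naive all-offsets loop over per-position set membership.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracleRevComp <- function(pattern) {
  chars <- rev(strsplit(pattern, "")[[1]])
  paste(ORACLE_COMP[chars], collapse = "")
}

# naive all-offsets scan; returns data.frame(start, strand)
oracleScan <- function(seq, pattern, strands = "forward") {
  pats <- list("+" = pattern)
  if (strands == "both") pats[["-"]] <- oracleRevComp(pattern)
  seq_chars <- strsplit(toupper(seq), "")[[1]]
  out <- data.frame(start = integer(0), strand = character(0))
  for (strand in names(pats)) {
    pchars <- strsplit(pats[[strand]], "")[[1]]
    L <- length(pchars)
    n <- length(seq_chars)
    if (n >= L) {
      for (s in 1:(n - L + 1)) {
        ok <- TRUE
        for (k in seq_len(L)) {
          base <- seq_chars[s + k - 1]
          # subject characters outside ACGT never match any motif position
          if (!base %in% c("A", "C", "G", "T") ||
              !base %in% ORACLE_IUPAC[[pchars[k]]]) {
            ok <- FALSE
            break
          }
        }
        if (ok) out <- rbind(out, data.frame(start = s, strand = strand))
      }
    }
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

randomSeq <- function(n, probs = rep(0.25, 4),
                      alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE, prob = probs), collapse = "")
}

randomPattern <- function(len) {
  # mostly fixed bases with occasional degenerate codes, as real consensus
  # motifs are
  letters <- names(ORACLE_IUPAC)
  w <- c(rep(5, 4), rep(1, 11))
  paste(sample(letters, len, replace = TRUE, prob = w), collapse = "")
}

randomAlignment <- function(id, n_rows = 3, n_cols = 40, gap_prob = 0.05) {
  rows <- vapply(seq_len(n_rows), function(i) {
    chars <- sample(c("A", "C", "G", "T"), n_cols, replace = TRUE)
    gaps <- runif(n_cols) < gap_prob
    # keep at least one non-gap character per row
    if (all(gaps)) gaps[sample.int(n_cols, 1)] <- FALSE
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  }, character(1))
  cneAlignment(id, setNames(rows, paste0("sp", seq_len(n_rows))))
}

# per-base bitmap oracle for interval overlap on a small toy genome
oracleOverlap <- function(a, b, genome_size = 10000) {
  bit_a <- logical(genome_size)
  bit_b <- logical(genome_size)
  for (i in seq_len(nrow(a))) bit_a[(a$start[i] + 1):a$end[i]] <- TRUE
  for (i in seq_len(nrow(b))) bit_b[(b$start[i] + 1):b$end[i]] <- TRUE
  n_a <- sum(vapply(seq_len(nrow(a)), function(i)
    any(bit_b[(a$start[i] + 1):a$end[i]]), logical(1)))
  n_b <- sum(vapply(seq_len(nrow(b)), function(i)
    any(bit_a[(b$start[i] + 1):b$end[i]]), logical(1)))
  shared <- sum(bit_a & bit_b)
  list(n_a = n_a, n_b = n_b, shared = shared,
       frac_a = shared / sum(bit_a), frac_b = shared / sum(bit_b))
}

randomIntervals <- function(n, genome_size = 10000, max_len = 400) {
  start <- sample.int(genome_size - max_len, n)
  width <- sample.int(max_len, n)
  data.frame(chrom = "toy", start = start, end = start + width)
}
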