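---
title: "Conserved Pbx-Hox motif scanning and enrichment: methods"
author: "cneMotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved Pbx-Hox motif scanning and enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cneMotifs)
```

# The problem

Conserved non-coding elements (CNEs) are short genomic regions — roughly
100–200 bp, AT-rich, typically enhancer-like — retained across distant
vertebrates. A recurring question in regulatory genomics is which
transcription-factor binding sites inside them explain their activity.
`cneMotifs` implements a phylogenetic-footprinting answer for degenerate
consensus motifs such as the Pbx-Hox site (core consensus `TGATNNAT`, its
stringent extension `TGATNNATKR` with K = G/T and R = A/G) and the Meis
site (`TGACAR`): a site is called *conserved* only if it appears gap-free
at the exact same aligned columns, on the same strand, in **every** row of
a multi-species CNE alignment. Because consensus matching has no score or
threshold, significance has to come from resampling; the package provides
the three null models such an analysis needs, plus density tests, per-locus
tests and position frequency matrices.

# Matching model

A motif is a string over the 15-letter IUPAC alphabet; each position is a
set of allowed bases (`N` = all four, `K` = {G,T}, ...). A window matches
iff every position's subject base lies in the motif's set. Three
conventions matter and are fixed package-wide:

* **Ambiguous subject bases never match.** A subject `N` (or gap) fails
  every motif position, including pattern `N`. This is conservative: an
  uncertain base is never counted as a site.
* **Overlapping hits are all counted.** No greedy masking — density
  statistics need the unbiased occurrence count.
* **Strand convention.** The default is forward-strand-only counting of
  the written consensus; every scanning and enrichment function takes
  `strands = "both"` to also match the reverse complement (minus-strand
  hits are reported in forward coordinates with the matched text in motif
  orientation). Every result object records which convention produced its
  counts. Forward-only is the minimal reading of counting "occurrences" of
  a written consensus; published occurrence counts for this motif family
  do not state the convention, so the package makes it explicit instead.

# The three null models

**Shuffled motif families** (single-species sets). The count of a motif is
compared with the counts of composition-matched shuffled variants. For
motifs shaped like `[4-base prefix][N block][2-base core][fixed suffix]`
(both `TGATNNAT` and `TGATNNATKR` qualify) the family is every distinct
ordering of the prefix letter multiset crossed with the core and its
reversal, degenerate positions held fixed in place — 12 × 2 = 24 members
for `TGATNNATKR`, the canonical published family. Motifs outside this
scheme (e.g. `TGACAR`) fall back to permuting the letter multiset of all
fixed positions, flagged `"generic"` in the output; the strict scheme can
be requested with `scheme = "prefix_core"`, which rejects such motifs.
The z-score uses the mean and *sample* (n−1) SD over **all** member
counts, including the original motif's own count; this is the convention
under which the published family tables' printed means (total/24) and SDs
are reproduced exactly, and it is pinned by the acceptance tests. The
p-value is the one-sided upper-tail normal probability — enrichment only.

**Column-shuffled alignments** (conserved hits). Each replicate applies
one shared random permutation to the columns of every alignment: the
per-column vertical content (hence per-column conservation) is preserved
exactly, while positional motif structure is destroyed. Whole-dataset
observed counts are compared with replicate counts; fold enrichment is
observed over null mean (reported infinite when the null mean is zero, and
0 when only the observed count is zero). Replicate `r` seeds the RNG with
`seed + r` and draws one permutation per alignment in order — reproducible
bit-for-bit, independent across replicates. Conserved motifs are counted
*per occurrence*, not per alignment.

**Markov-0 regeneration** (per-locus tests). Control sets regenerate every
locus sequence i.i.d. from the mononucleotide frequencies of the *whole*
CNE collection (never recomputed per locus, which would absorb real
composition signal). The z uses the sample SD of the control counts;
at least 2 control sets are required because the SD of one count is
undefined.

No multiple-testing correction is applied anywhere — single consensus
motifs are tested against bespoke nulls, mirroring how such enrichment
tables are usually reported; users comparing many motifs should correct
downstream. Results with p > 0.05 are flagged "N/S" by
`isSignificant()`; the threshold is an argument.

# Density and overlap accounting

`densityChiSquare()` is a 1-df goodness-of-fit chi-square with expected
counts proportional to total sequence lengths and **no continuity
correction** — the convention pinned by reproducing the published
hindbrain-positive vs hindbrain-negative comparison (64 motifs in 112 kb
vs 85 in 238 kb, p ≈ 0.0042). Lengths quoted in kb are kb × 1000;
lengths quoted in bp are used as printed. `overlapStats()` reports
element-level overlap counts and shared bases on *merged* interval sets
(0-based half-open internally; all human-facing hit tables are 1-based
inclusive, with BED6 export available).

# Position frequency matrices

`buildPfm()` tabulates per-position base counts over hit windows extended
by a 3′ flank in motif orientation (default 2 bases, turning 8-mer
`TGATNNAT` hits into the 10-column matrix in which the K/R positions 9–10
are visible). Hits whose flank runs off the element are dropped and
counted. For conserved alignment hits, build the PFM from the designated
reference species' ungapped row. `pfmToLogoTable()` adds per-position
Shannon information content, `2 + Σ f log2 f` bits (0 for uniform, 2 for a
pure column); output also serialises as a plain matrix or a MEME-minimal
block.

# The synthetic generator

`generateCneSet()` and `generateAlignmentSet()` exist so that every stage
can be validated against known truth without any external data. Defaults
were chosen once to emulate the study conditions this pipeline targets:
element length normal with mean 116 bp (the average CNE length in the
collections this method is used on) and SD 30, AT-biased background
(A 0.3, C 0.2, G 0.2, T 0.3), 4 species per alignment, per-branch
substitution rate 0.1 outside planted windows, gap rate 0.02. Planted
instances are Poisson per element, placed non-overlapping (an instance
that cannot be placed after 100 attempts is skipped with a warning), each
a uniform draw from the motif's concrete realizations. With
`scrub = TRUE`, background windows that match by chance are redrawn until
the set contains exactly the planted instances, making truth-table
recovery exact rather than statistical.

Two deliberate idealizations: substitutions and gaps never touch planted
windows (the model's premise — functional sites are the conserved blocks —
made literal), and gaps are single-row deletions, one row per gap column.
The generator therefore validates the *machinery*; it does not emulate
tree-structured rates, indel evolution, alignment error, or the spatial
clustering of real binding sites, so passing tests demonstrate
correctness of the computation, not robustness to real-alignment
artefacts.

# Numerical and degenerate-input choices

* Scanning is integer-code table lookup, vectorised over offsets; the
  test suite pins it against a naive all-offsets set-membership oracle
  (1,000 random cases, exact) and against `Biostrings::matchPattern()`
  on clean subjects.
* Empty or too-short sequences scan to zero hits, not errors; empty
  input *collections* are errors.
* `sd = 0` (all family counts equal, or degenerate control sets) leaves
  z and p as `NA` with a diagnostic note and a not-significant flag.
* Column shuffling of a 1-column alignment is the identity; fold
  enrichment conventions for zero means are given above.
* All resampling takes explicit integer seeds and is reproducible
  bit-for-bit; the pipeline manifest records seeds, parameters and input
  file digests, and reruns reproduce outputs byte-identically.

# Validation problem sizes

The shipped validation suite uses: 1,000-case scanner-oracle sweeps;
500-element planted-recovery sets; 40 four-species planted alignments with
1,000 shuffle replicates for fold enrichment; 100 motif-free alignment
datasets (20 alignments each, 200 replicates) for null-coverage
calibration, where the observed count should fall inside the central 95%
of the shuffled null in ≥ 90% of datasets; and 200 simulated loci of
30 × 300 bp uniform-composition sequences with 300 Markov-0 control sets
each for locus-z calibration (|mean z| < 0.15, SD within [0.8, 1.2]).
The calibration loci are larger than a typical CNE locus on purpose: with
20 × 116 bp the expected motif count per locus is ≈ 0.13 and the z-scores
are dominated by count discreteness, whereas ≈ 2 expected hits make the
normal approximation meaningful. These sizes are the package's choices for
a laptop-scale, deterministic validation; all are parameters, not limits.

# Known limitations

* Exact degenerate-consensus matching only — no PWM scoring, no
  mismatch tolerance; this is intentional fidelity to consensus-count
  methodology, not an oversight.
* The normal approximation to the family and control count distributions
  is inherited from the method being implemented; for very sparse counts
  (means near zero) the one-sided p-values are approximate, which is why
  the degenerate paths are flagged rather than extrapolated.
* De-novo motif discovery (PFM clustering, FDR estimation) is out of
  scope; the PFM module characterises *given* motifs' hit sets.
* The ClustalW reader handles standard interleaved `.aln` blocks; exotic
  dialects should be converted to aligned FASTA.
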