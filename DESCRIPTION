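Package: cneMotifs
Title: Conserved Pbx-Hox Motif Scanning and Enrichment in Conserved
    Non-Coding Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Phylogenetic footprinting of transcription-factor binding
    sites in conserved non-coding elements (CNEs). Scans DNA sequences and
    multi-species CNE alignments for degenerate IUPAC consensus motifs
    (e.g. the Pbx-Hox TGATNNAT / TGATNNATKR and Meis TGACAR sites),
    requiring conserved hits to occur gap-free at identical aligned
    positions in every species. Quantifies enrichment against three null
    models: column-shuffled alignments, permuted (shuffled) motif
    families, and Markov order-0 resampled sequences; adds chi-square
    motif-density comparisons between element classes, per-locus
    enrichment z-scores, position frequency matrices with information
    content for logo plotting, interval-overlap accounting between
    element collections, and a synthetic CNE/alignment generator with
    planted ground-truth motifs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: MotifAnnotation, SequenceMatching, Epigenetics,
    FunctionalGenomics
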