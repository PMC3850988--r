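Package: splicedb
Title: Synthetic Alternative-Splicing Junction-Peptide Databases for MS/MS Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds search-ready protein FASTA databases of alternative-splicing
    junction peptides from a genome and gene annotation. Exhaustively enumerates
    six elementary splicing event types per transcript (single exon, neighboring
    exon-exon, exon skipping, left/right intron retention junctions and retained
    introns), assembles flanked artificial splicing transcripts around each
    junction, and translates them using annotated exon phase or three-frame
    translation with longest junction-spanning peptide selection. Also provides
    the downstream analysis of search-engine peptide hits: novelty calling
    against a reference proteome, multi-sample reproducibility filtering,
    one-sided rank-based differential-presence marker testing, and gene-set
    context filtering. Includes a synthetic fixture generator with known ground
    truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    S4Vectors,
    GenomicRanges,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
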