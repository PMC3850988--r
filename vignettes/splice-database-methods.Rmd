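---
title: "Building and analyzing synthetic alternative-splicing peptide databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and analyzing synthetic alternative-splicing peptide databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicedb)
```

## The problem and the model

Database search engines identify MS/MS spectra by matching them against
theoretical fragmentations of peptides in a protein FASTA. A peptide from
an unannotated splice isoform — one that spans the junction of a skipped
exon, or reads into a retained intron — matches nothing in a conventional
proteome database and is lost. `splicedb` constructs the complementary
search space: for every transcript it enumerates all elementary splicing
events its exon/intron structure admits, synthesizes a nucleotide window
around each junction, and translates that window into a junction-spanning
peptide.

The enumeration is exhaustive by construction. A transcript with $E$ exons
and $I = E-1$ introns yields $E$ single-exon entries, $I$ neighboring
exon–exon junctions (the two together cover the normally spliced product
and serve as in-database controls), $\binom{E}{2} - (E-1)$ non-neighboring
exon–exon joins (exon skipping), $I$ exon–intron and $I$ intron–exon
junctions (the two edges of a retention event), and $I$ whole introns.
Mutually exclusive exons and alternative donor/acceptor sites are not
enumerated as separate types: they are expressible as co-occurring skips
and retention edges, so adding them would only duplicate search space.

The working assumption of the whole approach is that biologically absent
entries are harmless: a synthesized junction peptide that never exists in
the sample is simply never matched with a significant score. The cost of
exhaustiveness is search-space size, which is why the build supports
event-type masks and gene-set context restriction (building only the
entries of, say, a disease gene panel) — smaller databases mean better
statistical behavior of search scores and faster searches.

## Parameters that matter

* **Flank length** (`flank`, default 120 nt per side, so a 240-nt junction
  window). Translated, 120 nt is 40 residues — comfortably longer than the
  tryptic peptides (typically 7–25 residues) an engine will match, so every
  observable junction-spanning tryptic peptide is contained in the window.
  It is a configuration constant, not a hard-coded value, because the right
  figure follows from the digestion protocol's fragment-length
  distribution.
* **Minimum peptide length** (`min_peptide_length`, default 6 residues).
  Shorter sequences are effectively unidentifiable by search engines and
  only inflate the database.
* **E-value cutoff** (default 0.1) and **minimum sample count** (default
  2): the post-identification defaults; a peptide identified once, or only
  with weak scores, is not treated as observed.
* **Marker threshold** (`alpha`, default 0.05, unadjusted). The default
  mirrors common single-panel practice; Benjamini–Hochberg adjustment is
  available (`adjust = "BH"`) and advisable when many peptides are tested.

## Coordinate and translation conventions

All genomic intervals are 1-based inclusive end to end. GTF/GFF3 and the
Bioconductor interval stack (IRanges, `Biostrings::subseq`) share that
convention, so a single convention with no internal conversion layer is
the representation least likely to produce off-by-one errors in R.

Exon ordinals are computed from coordinates in 5'→3' transcript order
(reversed genomic order on the minus strand); an `exon_number` attribute
is only cross-checked, because its presence and reliability vary across
annotation dialects. Phase follows the GFF3 frame convention: phase $p$
means $p$ bases of the feature's first codon came from the previous exon,
so translation starts at offset $(3-p) \bmod 3$. Because an AST window
usually starts mid-exon, the phase recorded on a window is the *effective*
phase at the window start, $(p + s_0) \bmod 3$ for a window beginning
$s_0$ bases into the exon — frame bookkeeping stays exact across the
junction.

Phase-based translation is used only where a phase is defined: single-exon
and neighboring exon–exon entries whose annotation carries the frame
column. Every intron-containing event goes through three-frame
translation, since introns carry no phase; transcripts without phase
annotation route entirely to three-frame translation. Three-frame
selection translates all three offsets and keeps the frame whose
stop-free peptide *covering the splice site* is longest — not the longest
open reading frame anywhere in the window, which could lie entirely on one
side of the junction and carry no splicing information. Ties break to the
lowest frame offset, making builds deterministic.

Stop codons truncate rather than reject: the emitted peptide is the
maximal stop-free segment that still covers the junction, and an entry is
dropped only when no frame yields one. Codons containing ambiguity bases
translate as `X` and terminate a segment like a stop; features with more
than 10% `N` are flagged and their events dropped with a logged count,
since their translations would be mostly meaningless. When the junction
falls between codons, the notation inserts `^` at the boundary; when one
codon straddles it, that shared residue is wrapped in `()`. A peptide
counts as junction-covering if it has at least one residue on each side,
or contains the shared residue plus at least one neighbor.

## Windowing of single features

Single-feature entries (whole exons, whole introns) exist so that the
database also covers peptides internal to a retained feature, not only its
edges. A feature no longer than 240 nt is emitted whole. Longer features
are tiled into 240-nt windows stepping by 120 nt (the last window anchored
to the feature end), each window a separate database entry sharing the
mode string with a window-index suffix. The 120-nt overlap guarantees that
any ≤ 40-residue peptide internal to the feature lies wholly inside at
least one window; emitting a single window would silently drop coverage of
long introns. Junction flanks, by contrast, are drawn *only* from the two
joined features and truncate at their boundaries — extending a flank into
the next exon would smuggle a second junction into the entry and change
its semantics.

## The differential-presence test

Marker calling compares per-sample identification counts of each peptide
between two groups with a one-sided Wilcoxon rank-sum test (elevated
presence in the case group). The package uses the unpaired rank-sum form
by default because the intended design — independent case and control
cohorts — is unpaired; a signed-rank variant is available but requires an
explicit sample-pairing table, since applying a paired test to unpaired
data is not meaningful. For total sample counts up to 12 the p-value is
computed by full enumeration of all group labelings on midranks, which is
exact under ties (presence counts are heavily tied by nature); larger
designs use the tie-corrected normal approximation. Degenerate inputs
(all samples equal) return p = 1 with a flag. Reported alongside each
p-value are `h` and `c`, the distinct control- and case-sample counts in
which the peptide was seen.

Novelty calling is an exact substring search of the peptide in the
reference proteome, scoped by default to the proteins of the peptide's
*source gene*: a match in an unrelated gene's protein does not make the
peptide a known isoform of its own gene. A global scope and an optional
I/L-equivalence mode (isoleucine and leucine are isobaric to MS) are
provided; I/L collapsing is off by default so that novelty calls remain
sequence-exact unless the analyst opts into mass-level identity.

## What the fixture generator emulates — and what it does not

`generate_fixture()` plants single-transcript genes with configurable exon
counts, feature-length ranges and strand policy on one contig, separated
by ≥ 500 nt of random spacer so that flank windows of neighboring genes can
never overlap. Ground truth (coordinates and oriented sequences of every
feature) is written alongside, which is what makes round-trip and
strand-symmetry properties testable exactly. With
`plant_stop_free_frame = TRUE` (the default) every feature is scrubbed of
stop trinucleotides at *all three* offsets — each occurrence's middle base
is mutated to `C`, which cannot occur inside a stop codon, and the final
two bases are sealed to `C` so no stop can straddle a junction — making
every entry's translation succeed at full length and the per-type entry
counts exactly equal the enumeration formulas.

The generator's hit tables draw per-sample presence as independent
Bernoulli variables with group-specific probabilities and uniform(0, 0.05)
e-values for observed hits.

Deliberately not emulated: realistic codon usage and stop density, UTRs
and CDS boundaries, multi-transcript genes, overlapping genes, spectra and
retention times, engine score distributions, and decoys. Passing tests
therefore demonstrate the correctness of enumeration, windowing,
translation arithmetic, export determinism and the statistics — not
identification performance on real spectra, which depends on the search
engine and sample.

## Problem sizes and numerical choices

The verification suite works at desk scale by design: enumeration is
checked against a quadratic brute-force oracle on 200 random transcripts
of 1–12 exons; frame selection against an independently written naive
translator on 1,000 random junction windows; the exact rank test against
full 252-labeling enumeration for every 5-vs-5 presence configuration (to
within 1e-12); and the end-to-end analysis on a planted skipped-exon
marker in a 5-vs-5 design. Builds are byte-deterministic given inputs and
configuration — entry ids are derived from (transcript, mode, type, frame,
window), with no timestamps or RNG in the build path — which the suite
asserts by comparing complete output files.

## Known limitations

* Events are enumerated within one transcript; junctions joining features
  of different transcripts of the same gene are not synthesized (each
  transcript's own annotation already defines its feature set, and
  cross-transcript joins would square the search space).
* Duplicate peptides arising from different transcripts of a gene are kept
  by default for per-transcript accounting; `dedupe = TRUE` collapses
  byte-identical sequences, keeping the first entry id in sort order.
* No in-silico digestion or PTM enumeration: digestion is the search
  engine's job, and modified-peptide search spaces are a different
  problem.
* The reference-proteome novelty call is substring-exact; it does not
  model near-identical paralogs or sequence variants.
* Exact rank-test enumeration is limited to 12 samples
  (`choose(12, 6) = 924` labelings); beyond that the tie-corrected normal
  approximation is standard and accurate.
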