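# Independent oracles used by the property and acceptance tests. These are
# deliberately written against different primitives than the package code
# (hardcoded codon string instead of a lookup table, interval arithmetic
# instead of run bookkeeping, pairwise U statistic instead of rank sums).

# --- naive translator -------------------------------------------------------

# Standard genetic code as the classic 64-letter string in TCAG order.
.ORACLE_AA <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  "")[[1]]
.ORACLE_BASES <- c(T = 0L, C = 1L, A = 2L, G = 3L)

naive_translate <- function(seq, off) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  out <- character(0)
  i <- off + 1L
  while (i + 2L <= n) {
    idx <- .ORACLE_BASES[ch[i:(i + 2L)]]
    out <- c(out, if (any(is.na(idx))) "X"
             else .ORACLE_AA[16L * idx[1] + 4L * idx[2] + idx[3] + 1L])
    i <- i + 3L
  }
  out
}

# Longest stop-free junction-covering peptide length in one frame, by
# residue-interval arithmetic. J = nt contributed by the left feature.
naive_junction_span <- function(seq, off, J) {
  aa <- naive_translate(seq, off)
  if (length(aa) == 0L || J <= off) return(0L)
  ok <- !(aa %in% c("*", "X"))
  # residue k covers nucleotides (off + 3k - 2) .. (off + 3k)
  covers_left <- function(k) off + 3L * k - 2L <= J
  covers_right <- function(k) off + 3L * k >= J + 1L
  best <- 0L
  for (a in seq_along(aa)) {
    if (!ok[a]) next
    b <- a
    while (b < length(aa) && ok[b + 1L]) b <- b + 1L
    has_left <- any(vapply(a:b, covers_left, logical(1)))
    has_right <- any(vapply(a:b, covers_right, logical(1)))
    shared <- any(vapply(a:b, function(k) covers_left(k) && covers_right(k),
                         logical(1)))
    covered <- if (shared) (b - a + 1L) >= 2L else has_left && has_right
    if (covered) best <- max(best, b - a + 1L)
    # skip to end of run
    if (b > a) { }
  }
  best
}

# --- brute-force event enumeration ------------------------------------------

# Quadratic enumeration over all ordered feature pairs plus singles for a
# transcript with E exons; returns the per-type counts.
brute_force_event_counts <- function(E) {
  I <- max(E - 1L, 0L)
  feats <- rbind(
    data.frame(kind = "E", ord = seq_len(E)),
    if (I > 0L) data.frame(kind = "i", ord = seq_len(I))
  )
  counts <- c(EXON_NM = 0L, E_E_NM = 0L, E_I_AS = 0L, I_E_AS = 0L,
              E_E_AS = 0L, INTRON_AS = 0L)
  for (a in seq_len(nrow(feats))) {
    if (feats$kind[a] == "E") counts["EXON_NM"] <- counts["EXON_NM"] + 1L
    else counts["INTRON_AS"] <- counts["INTRON_AS"] + 1L
    for (b in seq_len(nrow(feats))) {
      ka <- feats$kind[a]; kb <- feats$kind[b]
      oa <- feats$ord[a]; ob <- feats$ord[b]
      if (ka == "E" && kb == "E" && ob == oa + 1L)
        counts["E_E_NM"] <- counts["E_E_NM"] + 1L
      if (ka == "E" && kb == "E" && ob >= oa + 2L)
        counts["E_E_AS"] <- counts["E_E_AS"] + 1L
      if (ka == "E" && kb == "i" && ob == oa)
        counts["E_I_AS"] <- counts["E_I_AS"] + 1L
      if (ka == "i" && kb == "E" && ob == oa + 1L)
        counts["I_E_AS"] <- counts["I_E_AS"] + 1L
    }
  }
  counts
}

# --- exhaustive permutation oracle for the one-sided rank test --------------

# One-sided p-value for elevated values in x_case, by enumerating every
# assignment of the pooled observations to the case group and comparing the
# Mann-Whitney U statistic (pairwise wins + half-ties).
perm_rank_oracle <- function(x_case, x_ctrl) {
  pooled <- c(x_case, x_ctrl)
  n <- length(pooled)
  nc <- length(x_case)
  u_stat <- function(case_idx) {
    xc <- pooled[case_idx]; xt <- pooled[-case_idx]
    sum(outer(xc, xt, ">")) + 0.5 * sum(outer(xc, xt, "=="))
  }
  u_obs <- u_stat(seq_len(nc))
  cmb <- utils::combn(n, nc)
  u_all <- apply(cmb, 2L, u_stat)
  mean(u_all >= u_obs - 1e-9)
}

# --- misc helpers ------------------------------------------------------------

# Minimal AST stub for translation tests (only the fields the translators use).
make_ast_stub <- function(sequence, junction_offset = NA_integer_,
                          phase = NA_integer_) {
  structure(list(
    event = data.frame(transcript_id = "TXTEST", gene_id = "GTEST",
                       type = "I_E_AS", mode = "i1E2",
                       stringsAsFactors = FALSE),
    sequence = sequence, junction_offset = junction_offset,
    left_truncated = FALSE, right_truncated = FALSE,
    window = NA_integer_, n_windows = 1L, phase = phase,
    contig = "chrT", strand = "+",
    left_coords = c(start = 1L, end = nchar(sequence))
  ), class = "splice_ast")
}

# Random nucleotide string (uses the ambient RNG; callers set seeds).
rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

# Write a tiny hand-rolled GTF.
write_toy_gtf <- function(path, rows) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";%s',
                   rows$gene_id, rows$transcript_id, rows$gene_name,
                   ifelse(is.na(rows$exon_number), "",
                          sprintf(' exon_number "%d";', rows$exon_number)))
  writeLines(paste(rows$contig, "toy", "exon", rows$start, rows$end, ".",
                   rows$strand,
                   ifelse(is.na(rows$phase), ".", as.character(rows$phase)),
                   attrs, sep = "\t"), path)
}

write_toy_fasta <- function(path, seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  path
}

# Default 1-gene / 4-exon all-plus fixture used across tests.
default_fixture <- function(seed = 7, dir = NULL, ...) {
  generate_fixture(fixture_spec(
    n_genes = 1, exons_per_gene = 4,
    exon_length_range = 200, intron_length_range = 200,
    strand_policy = "all_plus", seed = seed, ...), dir = dir)
}
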