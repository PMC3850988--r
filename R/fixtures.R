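# Synthetic fixtures with known ground truth: toy genomes + GTF annotations
# whose every exon/intron sequence is recorded, and per-sample peptide-hit
# tables with planted presence probabilities.

with_fixed_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Remove every stop trinucleotide (TAA/TAG/TGA) at *any* offset by mutating
# its middle base to C (C cannot occur inside a stop codon), iterating until
# clean. A feature processed this way is stop-free in all three frames; with
# a C-forced tail no stop can straddle a junction into the next feature
# either.
make_stop_free <- function(seq, seal_ends = TRUE) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  repeat {
    str <- paste(s, collapse = "")
    hit <- regexpr("T(AA|AG|GA)", str)
    if (hit < 0L) break
    s[hit + 1L] <- "C"
  }
  n <- length(s)
  if (seal_ends && n >= 2L) s[c(n - 1L, n)] <- "C"
  paste(s, collapse = "")
}

#' Specification for a synthetic genome fixture
#'
#' @param n_genes Number of genes (one transcript each).
#' @param exons_per_gene Exon count per gene, scalar or length-2 range.
#' @param exon_length_range,intron_length_range Feature length ranges in nt.
#' @param strand_policy `"all_plus"`, `"all_minus"` or `"mixed"`
#'   (alternating +/-).
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param plant_stop_free_frame Scrub stop codons from every feature (in all
#'   three frames, with sealed feature ends) so each entry is guaranteed a
#'   full-length translation.
#' @param spacer_length Random spacer between genes (>= 500 nt keeps flank
#'   windows of different genes disjoint).
#' @param contig_id Name of the single contig.
#' @param emit_phase Write exon phase into the GTF frame column.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 2L, exons_per_gene = 4L,
                         exon_length_range = c(150L, 300L),
                         intron_length_range = c(150L, 400L),
                         strand_policy = c("mixed", "all_plus", "all_minus"),
                         seed = 1L, plant_stop_free_frame = TRUE,
                         spacer_length = 500L, contig_id = "chrF",
                         emit_phase = TRUE) {
  strand_policy <- match.arg(strand_policy)
  rng <- function(x) if (length(x) == 1L) c(x, x) else as.integer(x[1:2])
  exon_length_range <- rng(exon_length_range)
  intron_length_range <- rng(intron_length_range)
  stopifnot(n_genes >= 1L, min(exon_length_range) >= 3L,
            min(intron_length_range) >= 3L, spacer_length >= 1L)
  structure(list(
    n_genes = as.integer(n_genes),
    exons_per_gene = rng(exons_per_gene),
    exon_length_range = exon_length_range,
    intron_length_range = intron_length_range,
    strand_policy = strand_policy,
    seed = as.integer(seed),
    plant_stop_free_frame = isTRUE(plant_stop_free_frame),
    spacer_length = as.integer(spacer_length),
    contig_id = contig_id,
    emit_phase = isTRUE(emit_phase)
  ), class = "fixture_spec")
}

#' Generate a synthetic genome, GTF annotation and ground-truth table
#'
#' Plants `n_genes` single-transcript genes on one contig, separated by
#' random spacer sequence. The ground truth lists every exon and intron
#' with coordinates and its transcript-oriented sequence, so downstream
#' extraction can be verified exactly. With `plant_stop_free_frame`, every
#' feature (and any junction window drawn from two features) translates
#' stop-free in all three frames.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed); when `NULL`, nothing is
#'   written and only in-memory objects are returned.
#' @return List with `genome_path`, `annotation_path`, `truth_path` (NULL
#'   when `dir` is NULL), `genome` (DNAStringSet), `truth` (data frame) and
#'   `gtf` (data frame of exon rows).
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixed_seed(spec$seed, {
    ri <- function(r) if (r[1] == r[2]) r[1] else sample(seq.int(r[1], r[2]), 1L)
    gen_seq <- function(n) {
      s <- random_nt(n)
      if (spec$plant_stop_free_frame) s <- make_stop_free(s) else s
    }
    contig_parts <- character(0)
    pos <- 0L
    truth <- list()
    gtf <- list()

    for (g in seq_len(spec$n_genes)) {
      gene_id <- sprintf("GENE%03d", g)
      tid <- sprintf("TX%03d", g)
      gname <- sprintf("FixGene%d", g)
      strand <- switch(spec$strand_policy,
        all_plus = "+", all_minus = "-",
        mixed = if (g %% 2L == 1L) "+" else "-")
      n_ex <- ri(spec$exons_per_gene)

      kinds <- character(0); ords <- integer(0)
      seqs <- character(0)
      for (k in seq_len(n_ex)) {
        kinds <- c(kinds, "exon"); ords <- c(ords, k)
        seqs <- c(seqs, gen_seq(ri(spec$exon_length_range)))
        if (k < n_ex) {
          kinds <- c(kinds, "intron"); ords <- c(ords, k)
          seqs <- c(seqs, gen_seq(ri(spec$intron_length_range)))
        }
      }
      lens <- nchar(seqs)
      block_oriented <- paste(seqs, collapse = "")
      B <- sum(lens)

      spacer <- random_nt(spec$spacer_length)
      contig_parts <- c(contig_parts, spacer)
      block_start <- pos + spec$spacer_length + 1L
      pos <- pos + spec$spacer_length + B

      block_genomic <- if (strand == "-") {
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(block_oriented)))
      } else block_oriented
      contig_parts <- c(contig_parts, block_genomic)

      offs <- cumsum(c(0L, lens[-length(lens)]))  # oriented 0-based offsets
      exon_cumlen <- 0L
      for (j in seq_along(seqs)) {
        if (strand == "-") {
          start_g <- block_start + (B - (offs[j] + lens[j]))
          end_g <- block_start + (B - offs[j]) - 1L
        } else {
          start_g <- block_start + offs[j]
          end_g <- block_start + offs[j] + lens[j] - 1L
        }
        phase <- NA_integer_
        if (kinds[j] == "exon") {
          phase <- exon_cumlen %% 3L
          exon_cumlen <- exon_cumlen + lens[j]
          gtf[[length(gtf) + 1L]] <- data.frame(
            contig = spec$contig_id, start = start_g, end = end_g,
            strand = strand, phase = if (spec$emit_phase) phase else NA_integer_,
            gene_id = gene_id, transcript_id = tid, gene_name = gname,
            exon_number = ords[j], stringsAsFactors = FALSE
          )
        }
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = gene_id, transcript_id = tid, kind = kinds[j],
          ordinal = ords[j], contig = spec$contig_id,
          start = start_g, end = end_g, strand = strand,
          phase = phase, sequence = seqs[j], stringsAsFactors = FALSE
        )
      }
    }
    contig_parts <- c(contig_parts, random_nt(spec$spacer_length))

    genome <- Biostrings::DNAStringSet(paste(contig_parts, collapse = ""))
    names(genome) <- spec$contig_id
    truth <- do.call(rbind, truth)
    gtf <- do.call(rbind, gtf)
    gtf <- gtf[order(gtf$start), , drop = FALSE]
    rownames(gtf) <- NULL

    out <- list(genome_path = NULL, annotation_path = NULL, truth_path = NULL,
                genome = genome, truth = truth, gtf = gtf)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      out$genome_path <- file.path(dir, "genome.fa")
      out$annotation_path <- file.path(dir, "annotation.gtf")
      out$truth_path <- file.path(dir, "ground_truth.tsv")
      Biostrings::writeXStringSet(genome, out$genome_path, width = 70L)
      attrs <- sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_name "%s"; exon_number "%d";',
        gtf$gene_id, gtf$transcript_id, gtf$gene_name, gtf$exon_number)
      lines <- paste(gtf$contig, "fixture", "exon", gtf$start, gtf$end, ".",
                     gtf$strand,
                     ifelse(is.na(gtf$phase), ".", as.character(gtf$phase)),
                     attrs, sep = "\t")
      writeLines(lines, out$annotation_path)
      utils::write.table(truth, out$truth_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    out
  })
}

#' Generate a per-sample peptide-hit table with planted presence
#'
#' Emulates a two-group (control vs case) MS identification experiment: for
#' each database entry, each sample observes the peptide as a Bernoulli
#' draw with the group's presence probability; observed hits get e-values
#' drawn uniformly from (0, `evalue_max`).
#'
#' @param entries Entry data frame from [build_database()].
#' @param n_samples_per_group Samples per group.
#' @param presence Presence probabilities `c(control, case)`, recycled per
#'   entry, or a 2-column matrix with one row per entry.
#' @param seed Integer seed.
#' @param evalue_max Upper bound of the simulated e-values (default 0.05).
#' @param path Optional TSV output path.
#' @return Data frame with columns `sample_id`, `group`, `peptide`,
#'   `entry_id`, `evalue`.
#' @export
generate_hit_table <- function(entries, n_samples_per_group = 5L,
                               presence = c(0.5, 0.5), seed = 1L,
                               evalue_max = 0.05, path = NULL) {
  if (is.matrix(presence)) {
    stopifnot(ncol(presence) == 2L, nrow(presence) == nrow(entries))
    pm <- presence
  } else {
    stopifnot(length(presence) == 2L)
    pm <- matrix(rep(presence, each = nrow(entries)), ncol = 2L)
  }
  stopifnot(all(pm >= 0 & pm <= 1))
  samples <- data.frame(
    sample_id = c(sprintf("ctrl_%02d", seq_len(n_samples_per_group)),
                  sprintf("case_%02d", seq_len(n_samples_per_group))),
    group = rep(c("control", "case"), each = n_samples_per_group),
    stringsAsFactors = FALSE
  )
  with_fixed_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(entries))) {
      for (s in seq_len(nrow(samples))) {
        p <- pm[i, if (samples$group[s] == "control") 1L else 2L]
        if (stats::rbinom(1L, 1L, p) == 1L) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = samples$sample_id[s],
            group = samples$group[s],
            peptide = entries$peptide[i],
            entry_id = entries$entry_id[i],
            evalue = stats::runif(1L, 0, evalue_max),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    hits <- if (length(rows)) do.call(rbind, rows) else data.frame(
      sample_id = character(0), group = character(0), peptide = character(0),
      entry_id = character(0), evalue = numeric(0))
    if (!is.null(path)) {
      utils::write.table(hits, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    hits
  })
}

#' Reference proteome of the normal-splicing entries
#'
#' Builds a protein FASTA from the normal-splicing (`EXON_NM`, `E_E_NM`)
#' peptides of a build, headed by `gene=` attributes, for use as a
#' synthetic "known proteome" in novelty-calling tests: alternative
#' junction peptides (skips, retentions) are absent from it by
#' construction.
#'
#' @param entries Entry data frame.
#' @param path Optional FASTA output path.
#' @return AAStringSet.
#' @export
normal_splicing_proteome <- function(entries, path = NULL) {
  nm <- entries[entries$type %in% c("EXON_NM", "E_E_NM"), , drop = FALSE]
  aa <- Biostrings::AAStringSet(nm$peptide)
  names(aa) <- paste0("REF|", nm$entry_id, " gene=", nm$gene_id)
  if (!is.null(path)) Biostrings::writeXStringSet(aa, path, width = 60L)
  aa
}
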