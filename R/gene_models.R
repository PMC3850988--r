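# Transcript models: parse genome + annotation, derive introns, extract
# strand-aware feature sequences. All coordinates are 1-based inclusive
# genomic, the native convention of GTF/GFF3 and of Biostrings/IRanges.

#' Read a genome FASTA into a named DNAStringSet
#'
#' Contig names are truncated at the first whitespace, matching how
#' annotation files refer to them.
#'
#' @param path Path to a (possibly multi-record) nucleotide FASTA.
#' @return A [Biostrings::DNAStringSet] named by contig id.
#' @export
load_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (any(duplicated(names(genome)))) {
    stop("duplicated contig ids in genome FASTA: ",
         paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "))
  }
  genome
}

#' Extract a feature sequence in transcript orientation
#'
#' Returns the genomic subsequence `[start, end]` of `contig`; on the minus
#' strand the reverse complement is returned, so the result always reads
#' 5'->3' in transcript orientation.
#'
#' @param genome DNAStringSet from [load_genome()].
#' @param contig Contig id.
#' @param start,end 1-based inclusive genomic coordinates.
#' @param strand `"+"` or `"-"`.
#' @return Character scalar nucleotide sequence.
#' @export
feature_seq <- function(genome, contig, start, end, strand = "+") {
  if (!contig %in% names(genome)) {
    stop("contig not present in genome FASTA: ", contig)
  }
  len <- length(genome[[contig]])
  if (start < 1L || end > len) {
    stop(sprintf("feature [%d,%d] outside contig '%s' bounds (1..%d)",
                 start, end, contig, len))
  }
  s <- Biostrings::subseq(genome[[contig]], start, end)
  if (identical(strand, "-")) s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Derive introns from a transcript's exons
#'
#' Intron `i` fills the genomic gap between the exons of ordinal `i` and
#' `i + 1` (transcript order), so a transcript with `n` exons has `n - 1`
#' introns and a single-exon transcript has none.
#'
#' @param model A `transcript_model` (or any list with an `exons` data frame
#'   holding `ordinal`, `start`, `end` and a `strand` field).
#' @return Data frame with columns `ordinal`, `start`, `end`.
#' @export
derive_introns <- function(model) {
  ex <- model$exons[order(model$exons$ordinal), , drop = FALSE]
  n <- nrow(ex)
  if (n <= 1L) {
    return(data.frame(ordinal = integer(0), start = integer(0), end = integer(0)))
  }
  if (identical(model$strand, "-")) {
    # transcript order runs right-to-left on the genome
    intr <- data.frame(
      ordinal = seq_len(n - 1L),
      start   = ex$end[seq_len(n - 1L) + 1L] + 1L,
      end     = ex$start[seq_len(n - 1L)] - 1L
    )
  } else {
    intr <- data.frame(
      ordinal = seq_len(n - 1L),
      start   = ex$end[seq_len(n - 1L)] + 1L,
      end     = ex$start[seq_len(n - 1L) + 1L] - 1L
    )
  }
  if (any(intr$start > intr$end)) {
    stop("adjacent or overlapping exons leave no intron gap in transcript ",
         model$transcript_id)
  }
  intr
}

new_transcript_model <- function(transcript_id, gene_id, gene_name,
                                 contig, strand, exons) {
  m <- list(
    transcript_id = transcript_id,
    gene_id = gene_id,
    gene_name = gene_name,
    contig = contig,
    strand = strand,
    exons = exons
  )
  m$introns <- derive_introns(m)
  class(m) <- "transcript_model"
  m
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (gene %s/%s) %s%s: %d exons, %d introns\n",
              x$transcript_id, x$gene_id, x$gene_name, x$contig, x$strand,
              nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

feature_row <- function(model, kind, ordinal) {
  tab <- if (kind == "E") model$exons else model$introns
  row <- tab[tab$ordinal == ordinal, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("no %s with ordinal %d in transcript %s",
                 if (kind == "E") "exon" else "intron", ordinal,
                 model$transcript_id))
  }
  row
}

feature_length <- function(model, kind, ordinal) {
  row <- feature_row(model, kind, ordinal)
  row$end - row$start + 1L
}

n_fraction <- function(seq) {
  if (nchar(seq) == 0L) return(0)
  sum(strsplit(seq, "", fixed = TRUE)[[1]] == "N") / nchar(seq)
}

#' Load an annotation plus genome into transcript models
#'
#' Reads exon records from a GTF or GFF3 file (via rtracklayer, which exposes
#' the frame column as `phase` for both dialects) and the genome FASTA, and
#' builds one validated `transcript_model` per transcript. Exon ordinals are
#' assigned from coordinates in 5'->3' transcript order (reversed genomic
#' order on the minus strand); an `exon_number` attribute, when present, is
#' only cross-checked and a mismatch raises a warning. Exons or introns with
#' more than `max_n_frac` ambiguous (`N`) bases are flagged so that events
#' touching them can be dropped at build time.
#'
#' @param annotation_path GTF or GFF3 file with `exon` features carrying
#'   `gene_id` and `transcript_id` attributes (`gene_name` optional).
#' @param genome_path Genome FASTA containing every contig the annotation
#'   references.
#' @param max_n_frac Ambiguity threshold above which a feature is flagged.
#' @return List with `models` (named list of `transcript_model`) and
#'   `genome` (DNAStringSet).
#' @export
load_annotation <- function(annotation_path, genome_path, max_n_frac = 0.1) {
  genome <- load_genome(genome_path)
  gr <- rtracklayer::import(annotation_path)
  gr <- gr[!is.na(S4Vectors::mcols(gr)$type) & S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) stop("no exon records found in ", annotation_path)

  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id) || is.null(mc$gene_id)) {
    stop("annotation lacks transcript_id/gene_id attributes on exon records")
  }
  contigs <- as.character(GenomicRanges::seqnames(gr))
  missing <- setdiff(unique(contigs), names(genome))
  if (length(missing) > 0L) {
    stop("annotation references contigs absent from the genome FASTA: ",
         paste(missing, collapse = ", "))
  }

  df <- data.frame(
    contig = contigs,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = as.character(mc$transcript_id),
    gene_id = as.character(mc$gene_id),
    gene_name = if (!is.null(mc$gene_name)) as.character(mc$gene_name)
                else as.character(mc$gene_id),
    phase = if (!is.null(mc$phase)) as.integer(mc$phase) else NA_integer_,
    exon_number = if (!is.null(mc$exon_number)) as.character(mc$exon_number)
                  else NA_character_,
    stringsAsFactors = FALSE
  )

  models <- list()
  for (tid in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tid, , drop = FALSE]
    if (length(unique(sub$contig)) > 1L || length(unique(sub$strand)) > 1L) {
      warning("transcript ", tid, " spans multiple contigs/strands; skipped")
      next
    }
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] <= sub$end[-nrow(sub)])) {
      warning("transcript ", tid, " has overlapping exons; skipped")
      next
    }
    strand <- sub$strand[1L]
    if (!strand %in% c("+", "-")) strand <- "+"
    ord <- if (strand == "-") rev(seq_len(nrow(sub))) else seq_len(nrow(sub))
    exons <- data.frame(
      ordinal = ord,
      start = sub$start,
      end = sub$end,
      phase = sub$phase
    )
    exons <- exons[order(exons$ordinal), , drop = FALSE]
    rownames(exons) <- NULL
    if (!all(is.na(sub$exon_number))) {
      claimed <- suppressWarnings(as.integer(sub$exon_number))[order(ord)]
      if (!all(is.na(claimed)) &&
          !identical(claimed[!is.na(claimed)],
                     seq_len(nrow(sub))[!is.na(claimed)])) {
        warning("transcript ", tid,
                ": exon_number attribute disagrees with coordinate-derived ",
                "ordinals; coordinates win")
      }
    }
    m <- new_transcript_model(
      transcript_id = tid,
      gene_id = sub$gene_id[1L],
      gene_name = sub$gene_name[1L],
      contig = sub$contig[1L],
      strand = strand,
      exons = exons
    )
    m$exon_flagged <- vapply(seq_len(nrow(m$exons)), function(i) {
      n_fraction(feature_seq(genome, m$contig, m$exons$start[i],
                             m$exons$end[i], m$strand)) > max_n_frac
    }, logical(1))
    m$intron_flagged <- vapply(seq_len(nrow(m$introns)), function(i) {
      n_fraction(feature_seq(genome, m$contig, m$introns$start[i],
                             m$introns$end[i], m$strand)) > max_n_frac
    }, logical(1))
    models[[tid]] <- m
  }
  if (length(models) == 0L) stop("no valid transcripts parsed from ", annotation_path)
  list(models = models, genome = genome)
}

#' Spliced transcript sequence of a model
#'
#' Concatenates exon sequences in ordinal (5'->3') order.
#'
#' @param model A `transcript_model`.
#' @param genome DNAStringSet.
#' @return Character scalar.
#' @export
spliced_sequence <- function(model, genome) {
  ex <- model$exons[order(model$exons$ordinal), , drop = FALSE]
  paste(vapply(seq_len(nrow(ex)), function(i) {
    feature_seq(genome, model$contig, ex$start[i], ex$end[i], model$strand)
  }, character(1)), collapse = "")
}
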