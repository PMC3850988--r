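# Post-identification analysis of search-engine hits against the built
# database: e-value and reproducibility filtering, novelty calling against
# a reference proteome, and one-sided differential-presence marker testing.

#' Load a peptide-hit table
#'
#' Canonical exchange TSV with columns `sample_id`, `peptide`, `entry_id`,
#' `evalue` and optional `group`. Rows with non-positive e-values are
#' rejected; when `entries` is supplied, rows referencing unknown entry ids
#' are excluded with a message.
#'
#' @param path TSV path.
#' @param entries Optional entry data frame for referential validation.
#' @return Data frame of validated hits.
#' @export
load_hits <- function(path, entries = NULL) {
  hits <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "peptide", "entry_id", "evalue")
  miss <- setdiff(req, names(hits))
  if (length(miss) > 0L) {
    stop("hit table lacks required column(s): ", paste(miss, collapse = ", "))
  }
  bad <- !is.finite(hits$evalue) | hits$evalue <= 0
  if (any(bad)) {
    message(sum(bad), " hit row(s) with non-positive e-value rejected")
    hits <- hits[!bad, , drop = FALSE]
  }
  if (!is.null(entries)) {
    unknown <- !hits$entry_id %in% entries$entry_id
    if (any(unknown)) {
      message(sum(unknown), " hit row(s) referencing unknown entry ids excluded")
      hits <- hits[!unknown, , drop = FALSE]
    }
  }
  rownames(hits) <- NULL
  hits
}

#' Filter hits by e-value cutoff
#'
#' @param hits Hit data frame.
#' @param cutoff Maximum e-value retained (default 0.1).
#' @return Subset of `hits`.
#' @export
filter_evalue <- function(hits, cutoff = 0.1) {
  out <- hits[hits$evalue <= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Peptides reproduced in at least n samples
#'
#' Duplicate hits of a peptide within one sample count once.
#'
#' @param hits Hit data frame.
#' @param n Minimum number of distinct samples (default 2).
#' @return Character vector of retained peptide sequences.
#' @export
filter_min_samples <- function(hits, n = 2L) {
  if (nrow(hits) == 0L) return(character(0))
  counts <- tapply(hits$sample_id, hits$peptide,
                   function(s) length(unique(s)))
  names(counts)[counts >= n]
}

parse_proteome_genes <- function(proteome, gene_key = "gene") {
  pat <- paste0(gene_key, "=([^[:space:]]+)")
  m <- regmatches(names(proteome), regexec(pat, names(proteome)))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

#' Call splice-isoform novelty of peptides against a reference proteome
#'
#' A peptide is novel when it is not an exact substring of any annotated
#' protein in the chosen scope: `"gene"` restricts the haystack to proteins
#' of the peptide's source gene (so a hit in an unrelated gene does not veto
#' novelty); `"global"` searches the whole proteome. With `collapse_il`,
#' isoleucine and leucine are treated as indistinguishable (as they are by
#' mass).
#'
#' @param peptides Character vector of peptide sequences.
#' @param source_gene_ids Gene id of each peptide's database entry
#'   (recycled if scalar).
#' @param proteome AAStringSet or protein FASTA path; headers must carry
#'   `gene=<id>` (key configurable via `gene_key`).
#' @param scope `"gene"` (default) or `"global"`.
#' @param gene_key Header attribute naming the gene id.
#' @param collapse_il Treat I and L as equivalent.
#' @return Data frame with `peptide`, `gene_id`, `gene_scope_hit`,
#'   `global_hit`, `novel`.
#' @export
check_novelty <- function(peptides, source_gene_ids, proteome,
                          scope = c("gene", "global"), gene_key = "gene",
                          collapse_il = FALSE) {
  scope <- match.arg(scope)
  if (is.character(proteome) && length(proteome) == 1L && file.exists(proteome)) {
    proteome <- Biostrings::readAAStringSet(proteome)
  }
  prot_genes <- parse_proteome_genes(proteome, gene_key)
  prot_seqs <- as.character(proteome)
  if (length(source_gene_ids) == 1L) {
    source_gene_ids <- rep(source_gene_ids, length(peptides))
  }
  stopifnot(length(source_gene_ids) == length(peptides))
  norm <- function(x) if (collapse_il) gsub("I", "L", x, fixed = TRUE) else x
  prot_norm <- norm(prot_seqs)

  res <- lapply(seq_along(peptides), function(i) {
    pep <- norm(peptides[i])
    gid <- source_gene_ids[i]
    in_gene_scope <- !is.na(prot_genes) & prot_genes == gid
    if (!any(in_gene_scope)) {
      warning("source gene ", gid,
              " absent from the reference proteome; peptide trivially novel ",
              "in gene scope")
    }
    gene_hit <- any(grepl(pep, prot_norm[in_gene_scope], fixed = TRUE))
    global_hit <- any(grepl(pep, prot_norm, fixed = TRUE))
    data.frame(peptide = peptides[i], gene_id = gid,
               gene_scope_hit = gene_hit, global_hit = global_hit,
               novel = if (scope == "gene") !gene_hit else !global_hit,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Exact one-sided rank-sum p-value by full enumeration of group labelings.
# Handles ties through midranks; used for small designs where the normal
# approximation is poor.
rank_sum_exact_p <- function(x_case, x_ctrl) {
  v <- c(x_case, x_ctrl)
  r <- rank(v)
  n <- length(v)
  nc <- length(x_case)
  w_obs <- sum(r[seq_len(nc)])
  cmb <- utils::combn(n, nc)
  w_all <- colSums(matrix(r[cmb], nrow = nc))
  mean(w_all >= w_obs - 1e-9)
}

#' One-sided differential-presence test per peptide
#'
#' Compares per-sample identification counts of each peptide between two
#' sample groups with a one-sided Wilcoxon rank-sum test of elevated
#' presence in the case group. Designs with <= `exact_max_n` total samples
#' get exact permutation p-values (full enumeration of group labelings,
#' tie-safe); larger designs use the normal approximation with tie
#' correction. Samples without a hit contribute a count of zero, so the
#' full sample roster must be supplied.
#'
#' @param hits Hit data frame (post filtering).
#' @param groups Data frame with columns `sample_id`, `group` listing every
#'   sample, or a named character vector `sample_id -> group`.
#' @param case_group Label of the group tested for elevated presence.
#' @param method `"rank_sum"` (default, unpaired) or `"signed_rank"`
#'   (paired; requires `pairs`).
#' @param pairs For `signed_rank`: data frame with columns `case_sample`,
#'   `control_sample` defining the pairing.
#' @param presence_only Reduce counts to binary presence before testing.
#' @param exact_max_n Largest total sample count for exact enumeration
#'   (default 12).
#' @return Data frame sorted by ascending p-value with columns `peptide`,
#'   `entry_id`, `h` (distinct control samples with the peptide), `c`
#'   (distinct case samples), `p_value`, `direction`, `degenerate`.
#' @export
differential_presence <- function(hits, groups, case_group = "case",
                                  method = c("rank_sum", "signed_rank"),
                                  pairs = NULL, presence_only = FALSE,
                                  exact_max_n = 12L) {
  method <- match.arg(method)
  if (!is.data.frame(groups)) {
    groups <- data.frame(sample_id = names(groups), group = unname(groups),
                         stringsAsFactors = FALSE)
  }
  glabs <- unique(groups$group)
  if (length(glabs) != 2L) stop("exactly two groups are required")
  if (!case_group %in% glabs) stop("case_group '", case_group, "' not in groups")
  ctrl_group <- setdiff(glabs, case_group)
  case_samples <- groups$sample_id[groups$group == case_group]
  ctrl_samples <- groups$sample_id[groups$group == ctrl_group]
  if (length(case_samples) < 2L || length(ctrl_samples) < 2L) {
    stop("each group needs >= 2 samples")
  }
  if (method == "signed_rank") {
    if (is.null(pairs)) {
      stop("signed_rank requires an explicit sample pairing ('pairs')")
    }
    stopifnot(all(c("case_sample", "control_sample") %in% names(pairs)))
  }

  peptides <- unique(hits$peptide)
  res <- lapply(peptides, function(pep) {
    sub <- hits[hits$peptide == pep, , drop = FALSE]
    cnt <- function(samples) {
      vapply(samples, function(s) sum(sub$sample_id == s), numeric(1))
    }
    x_case <- cnt(case_samples)
    x_ctrl <- cnt(ctrl_samples)
    if (presence_only) {
      x_case <- as.numeric(x_case > 0); x_ctrl <- as.numeric(x_ctrl > 0)
    }
    degenerate <- length(unique(c(x_case, x_ctrl))) == 1L
    p <- if (degenerate) {
      1
    } else if (method == "signed_rank") {
      xc <- cnt(pairs$case_sample); xt <- cnt(pairs$control_sample)
      suppressWarnings(stats::wilcox.test(
        xc, xt, paired = TRUE, alternative = "greater",
        exact = FALSE, correct = TRUE)$p.value)
    } else if (length(x_case) + length(x_ctrl) <= exact_max_n) {
      rank_sum_exact_p(x_case, x_ctrl)
    } else {
      suppressWarnings(stats::wilcox.test(
        x_case, x_ctrl, alternative = "greater",
        exact = FALSE, correct = TRUE)$p.value)
    }
    data.frame(
      peptide = pep,
      entry_id = sub$entry_id[1L],
      h = length(unique(sub$sample_id[sub$sample_id %in% ctrl_samples])),
      c = length(unique(sub$sample_id[sub$sample_id %in% case_samples])),
      p_value = p,
      direction = if (mean(x_case) > mean(x_ctrl)) "up_in_case"
                  else if (mean(x_case) < mean(x_ctrl)) "down_in_case"
                  else "equal",
      degenerate = degenerate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p_value, out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call differential-presence markers
#'
#' Markers are peptides with `p < alpha` (no multiplicity adjustment by
#' default; `adjust = "BH"` applies Benjamini--Hochberg first).
#'
#' @param results Data frame from [differential_presence()].
#' @param alpha Significance threshold (default 0.05).
#' @param adjust `"none"` or `"BH"`.
#' @return Subset of `results` (with `p_adjusted` when adjusted).
#' @export
call_markers <- function(results, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p <- results$p_value
  if (adjust == "BH") {
    results$p_adjusted <- stats::p.adjust(p, method = "BH")
    p <- results$p_adjusted
  }
  out <- results[p < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate hits with database entry metadata
#'
#' Joins hit rows to entries on `entry_id`, adding gene, transcript, mode,
#' type, class and junction notation.
#'
#' @param hits Hit data frame.
#' @param entries Entry data frame.
#' @return Annotated hit data frame.
#' @export
annotate_hits <- function(hits, entries) {
  cols <- c("entry_id", "gene_id", "gene_name", "transcript_id", "mode",
            "type", "class", "junction_notation")
  merge(hits, entries[cols], by = "entry_id", all.x = TRUE, sort = FALSE)
}

#' Full marker pipeline on a hit table
#'
#' Runs the post-identification chain: e-value filter, minimum-sample
#' reproducibility filter, differential-presence testing, marker calling,
#' and (when a reference proteome is given) novelty annotation. When
#' `require_novel`, only novel markers are reported.
#'
#' @param hits Hit data frame.
#' @param entries Entry data frame (for gene lookup / annotation).
#' @param groups Sample-to-group assignment (see
#'   [differential_presence()]).
#' @param case_group Case group label.
#' @param evalue_cutoff E-value cutoff (default 0.1).
#' @param min_samples Minimum distinct samples per peptide (default 2).
#' @param alpha Marker threshold (default 0.05).
#' @param adjust Multiplicity adjustment (`"none"` or `"BH"`).
#' @param proteome Optional reference proteome (AAStringSet or FASTA path)
#'   for novelty calling.
#' @param require_novel Keep only novel markers (needs `proteome`).
#' @param ... Passed to [differential_presence()].
#' @return Data frame of called markers annotated with entry metadata (and
#'   novelty columns when a proteome was given), plus a `counts` attribute
#'   with per-stage tallies.
#' @export
run_marker_analysis <- function(hits, entries, groups, case_group = "case",
                                evalue_cutoff = 0.1, min_samples = 2L,
                                alpha = 0.05, adjust = "none",
                                proteome = NULL, require_novel = FALSE, ...) {
  counts <- c(input = nrow(hits))
  hits <- filter_evalue(hits, evalue_cutoff)
  counts["evalue_pass"] <- nrow(hits)
  keep <- filter_min_samples(hits, min_samples)
  hits <- hits[hits$peptide %in% keep, , drop = FALSE]
  counts["reproducible_peptides"] <- length(keep)
  if (nrow(hits) == 0L) {
    out <- data.frame()
    attr(out, "counts") <- counts
    return(out)
  }
  res <- differential_presence(hits, groups, case_group = case_group, ...)
  markers <- call_markers(res, alpha = alpha, adjust = adjust)
  counts["markers"] <- nrow(markers)
  if (nrow(markers) > 0L) {
    idx <- match(markers$entry_id, entries$entry_id)
    meta <- entries[idx, c("gene_id", "gene_name", "transcript_id", "mode",
                           "type", "class", "junction_notation"),
                    drop = FALSE]
    markers <- cbind(markers, meta)
    rownames(markers) <- NULL
    if (!is.null(proteome)) {
      nov <- check_novelty(markers$peptide, markers$gene_id, proteome)
      markers$gene_scope_hit <- nov$gene_scope_hit
      markers$global_hit <- nov$global_hit
      markers$novel <- nov$novel
      if (require_novel) {
        markers <- markers[markers$novel, , drop = FALSE]
        rownames(markers) <- NULL
      }
      counts["novel_markers"] <- sum(nov$novel)
    }
  }
  attr(markers, "counts") <- counts
  markers
}
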