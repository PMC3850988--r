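# Build orchestration: models -> events -> ASTs -> peptides -> database
# entries, plus FASTA/TSV export and gene-set filtering.

#' Build configuration
#'
#' @param flank Flank length in nt on each side of a junction (default 120).
#' @param min_peptide_length Shortest peptide worth emitting (default 6;
#'   shorter peptides are not identifiable by MS search).
#' @param dedupe Collapse byte-identical peptide sequences, keeping the
#'   lexicographically smallest entry id.
#' @param types Event types to include (default all six).
#' @param gene_set Optional character vector of gene ids restricting the
#'   build context.
#' @return A `build_config` list.
#' @export
build_config <- function(flank = 120L, min_peptide_length = 6L,
                         dedupe = FALSE, types = EVENT_TYPES,
                         gene_set = NULL) {
  types <- toupper(types)
  bad <- setdiff(types, EVENT_TYPES)
  if (length(bad) > 0L) stop("unknown event types: ", paste(bad, collapse = ", "))
  structure(list(
    flank = as.integer(flank),
    min_peptide_length = as.integer(min_peptide_length),
    dedupe = isTRUE(dedupe),
    types = types,
    gene_set = gene_set
  ), class = "build_config")
}

entry_id <- function(transcript_id, mode, type, frame, window) {
  paste0("SASD|", transcript_id, "|", mode, "|", type, "|f", frame,
         ifelse(is.na(window), "", paste0("|w", window)))
}

event_touches_flagged <- function(model, ev) {
  flag <- function(kind, ord) {
    v <- if (kind == "E") model$exon_flagged else model$intron_flagged
    if (is.null(v)) FALSE else isTRUE(v[ord])
  }
  flag(ev$left_kind, ev$left_ord) ||
    (!is.na(ev$right_kind) && flag(ev$right_kind, ev$right_ord))
}

#' Build an alternative-splicing peptide database
#'
#' Runs the three-stage pipeline over every transcript model: enumerate the
#' six event types, assemble each event's flanked AST window(s), translate
#' (phase-based for exonic normal-splicing entries with known phase,
#' three-frame with longest-junction-peptide selection otherwise) and
#' collect surviving peptides as database entries. The manifest records the
#' configuration, per-type entry counts and per-reason drop counts.
#'
#' @param models Named list of `transcript_model` objects (from
#'   [load_annotation()]).
#' @param genome DNAStringSet.
#' @param config A [build_config()].
#' @return List with `entries` (data frame, one row per database entry) and
#'   `manifest` (list).
#' @export
build_database <- function(models, genome, config = build_config()) {
  if (inherits(models, "transcript_model")) models <- list(models)
  if (!is.null(config$gene_set)) {
    keep <- vapply(models, function(m) m$gene_id %in% config$gene_set, logical(1))
    models <- models[keep]
  }
  drops <- c(flagged_feature = 0L, no_translation = 0L, too_short = 0L)
  rows <- vector("list", 0L)

  for (model in models) {
    events <- enumerate_events(model)
    events <- events[events$type %in% config$types, , drop = FALSE]
    for (i in seq_len(nrow(events))) {
      ev <- events[i, , drop = FALSE]
      if (event_touches_flagged(model, ev)) {
        drops["flagged_feature"] <- drops["flagged_feature"] + 1L
        next
      }
      asts <- assemble_ast(ev, genome, model, flank = config$flank)
      for (ast in asts) {
        use_phase <- ev$type %in% c("EXON_NM", "E_E_NM") && !is.na(ast$phase)
        pep <- if (use_phase) translate_with_phase(ast)
               else translate_three_frames(ast)
        if (is.null(pep)) {
          drops["no_translation"] <- drops["no_translation"] + 1L
          next
        }
        if (nchar(pep$sequence) < config$min_peptide_length) {
          drops["too_short"] <- drops["too_short"] + 1L
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          entry_id = entry_id(model$transcript_id, ev$mode, ev$type,
                              pep$frame, ast$window),
          gene_id = model$gene_id,
          gene_name = model$gene_name,
          transcript_id = model$transcript_id,
          mode = ev$mode,
          type = ev$type,
          class = ev$class,
          frame = pep$frame,
          phase_used = pep$phase_used,
          window = ast$window,
          peptide = pep$sequence,
          junction_notation = pep$junction_notation,
          contig = ast$contig,
          strand = ast$strand,
          left_start = unname(ast$left_coords["start"]),
          left_end = unname(ast$left_coords["end"]),
          right_start = if (is.null(ast$right_coords)) NA_integer_
                        else unname(ast$right_coords["start"]),
          right_end = if (is.null(ast$right_coords)) NA_integer_
                      else unname(ast$right_coords["end"]),
          stringsAsFactors = FALSE
        )
      }
    }
  }

  if (length(rows) == 0L) {
    stop("database build produced no entries (",
         sum(drops), " candidates dropped)")
  }
  entries <- do.call(rbind, rows)
  rownames(entries) <- NULL
  if (anyDuplicated(entries$entry_id)) {
    stop("internal error: duplicated entry ids in build")
  }
  if (config$dedupe) {
    entries <- entries[order(entries$entry_id), , drop = FALSE]
    entries <- entries[!duplicated(entries$peptide), , drop = FALSE]
    rownames(entries) <- NULL
  }

  type_counts <- vapply(EVENT_TYPES, function(t) sum(entries$type == t),
                        integer(1))
  manifest <- list(
    flank = config$flank,
    min_peptide_length = config$min_peptide_length,
    dedupe = config$dedupe,
    types = paste(config$types, collapse = ","),
    gene_set = if (is.null(config$gene_set)) ""
               else paste(config$gene_set, collapse = ","),
    n_transcripts = length(models),
    n_entries = nrow(entries),
    type_counts = type_counts,
    drops = drops
  )
  list(entries = entries, manifest = manifest)
}

#' Write database entries as a search-ready protein FASTA
#'
#' One record per entry, 60-column wrapped. The default header is
#' `>SASD|<transcript>|<mode>|<type>|f<frame>[|w<window>] gene=<gene_id>
#' name=<gene_name>` so the full pipe-delimited token is the accession;
#' `header_style = "simple"` emits the bare entry id for engines with strict
#' accession parsing. Sequences are the bare peptides (junction markers
#' stripped).
#'
#' @param entries Entry data frame from [build_database()].
#' @param path Output FASTA path.
#' @param header_style `"full"` or `"simple"`.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(entries, path, header_style = c("full", "simple")) {
  header_style <- match.arg(header_style)
  if (nrow(entries) == 0L) stop("no entries to write")
  aa <- Biostrings::AAStringSet(entries$peptide)
  names(aa) <- if (header_style == "full") {
    paste0(entries$entry_id, " gene=", entries$gene_id,
           " name=", entries$gene_name)
  } else {
    entries$entry_id
  }
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Write gene, transcript and region views
#'
#' The gene view aggregates entry counts per type per gene; the transcript
#' view does the same per transcript; the region view lists one row per
#' entry with the genomic intervals of both AST parts, splicing type,
#' junction notation and peptide sequence (it round-trips the full entry
#' table).
#'
#' @param entries Entry data frame.
#' @param path_prefix Output prefix; writes
#'   `<prefix>_gene_view.tsv`, `<prefix>_transcript_view.tsv`,
#'   `<prefix>_region_view.tsv`.
#' @return Invisibly, named vector of the three paths.
#' @export
write_views <- function(entries, path_prefix) {
  count_view <- function(key_cols) {
    keys <- unique(entries[key_cols])
    rownames(keys) <- NULL
    for (t in EVENT_TYPES) {
      keys[[t]] <- vapply(seq_len(nrow(keys)), function(i) {
        sel <- rep(TRUE, nrow(entries))
        for (k in key_cols) sel <- sel & entries[[k]] == keys[[k]][i]
        sum(sel & entries$type == t)
      }, integer(1))
    }
    keys$total <- rowSums(keys[EVENT_TYPES])
    keys
  }
  paths <- c(
    gene = paste0(path_prefix, "_gene_view.tsv"),
    transcript = paste0(path_prefix, "_transcript_view.tsv"),
    region = paste0(path_prefix, "_region_view.tsv")
  )
  utils::write.table(count_view(c("gene_id", "gene_name")), paths["gene"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(count_view(c("gene_id", "transcript_id")),
                     paths["transcript"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(entries, paths["region"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read database entries back from a region view
#'
#' @param path A `*_region_view.tsv` written by [write_views()].
#' @return Entry data frame.
#' @export
read_region_view <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Restrict entries to a gene set
#'
#' Keeps exactly the entries whose `gene_id` is in `gene_set`, preserving
#' order. An empty intersection is a warning, not an error.
#'
#' @param entries Entry data frame.
#' @param gene_set Character vector of gene ids.
#' @return Subset of `entries`.
#' @export
filter_by_gene_set <- function(entries, gene_set) {
  out <- entries[entries$gene_id %in% gene_set, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("gene set does not intersect any build gene")
  out
}

#' Write a flat key=value build manifest
#'
#' @param manifest Manifest list from [build_database()].
#' @param path Output path.
#' @param inputs Optional named character vector of input file paths; md5
#'   checksums are recorded.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path, inputs = NULL) {
  lines <- character(0)
  add <- function(k, v) lines <<- c(lines, paste0(k, "=", v))
  for (k in c("flank", "min_peptide_length", "dedupe", "types", "gene_set",
              "n_transcripts", "n_entries")) {
    add(k, manifest[[k]])
  }
  for (t in names(manifest$type_counts)) {
    add(paste0("count_", t), manifest$type_counts[[t]])
  }
  for (d in names(manifest$drops)) add(paste0("drop_", d), manifest$drops[[d]])
  if (!is.null(inputs)) {
    sums <- tools::md5sum(inputs)
    for (i in seq_along(inputs)) {
      add(paste0("md5_", names(inputs)[i]), unname(sums[i]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
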