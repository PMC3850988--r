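# Enumeration of the six elementary splicing event types and assembly of
# artificial splicing transcripts (ASTs): flanked nucleotide windows around
# each junction, or (tiled) windows over single features.

EVENT_TYPES <- c("EXON_NM", "E_E_NM", "E_I_AS", "I_E_AS", "E_E_AS", "INTRON_AS")

EVENT_CLASS <- c(
  EXON_NM   = "Normal Splicing",
  E_E_NM    = "Normal Splicing",
  E_E_AS    = "Exon Skipping",
  E_I_AS    = "Intron Retention",
  I_E_AS    = "Intron Retention",
  INTRON_AS = "Intron Retention"
)

#' Splicing class of an event type
#'
#' Maps the six elementary event types onto the three splicing classes:
#' Normal Splicing (`EXON_NM`, `E_E_NM`), Exon Skipping (`E_E_AS`) and
#' Intron Retention (`E_I_AS`, `I_E_AS`, `INTRON_AS`).
#'
#' @param type Character vector of event type labels.
#' @return Character vector of class labels.
#' @export
event_class <- function(type) {
  cls <- EVENT_CLASS[toupper(type)]
  if (any(is.na(cls))) {
    stop("unknown event type: ", paste(type[is.na(cls)], collapse = ", "))
  }
  unname(cls)
}

#' Compact mode string of a junction event
#'
#' Emits the canonical separator-free descriptor: `"E2"` (single exon),
#' `"i6"` (retained intron), `"E1E2"` (neighboring exons), `"E1E3"`
#' (skip), `"E1i1"` (exon--intron), `"i3E4"` (intron--exon).
#'
#' @param type Event type label.
#' @param left_ord,right_ord Feature ordinals (`right_ord` `NA` for
#'   single-feature events).
#' @return Character scalar mode string.
#' @export
mode_string <- function(type, left_ord, right_ord = NA_integer_) {
  switch(toupper(type),
    EXON_NM   = sprintf("E%d", left_ord),
    INTRON_AS = sprintf("i%d", left_ord),
    E_E_NM    = sprintf("E%dE%d", left_ord, right_ord),
    E_E_AS    = sprintf("E%dE%d", left_ord, right_ord),
    E_I_AS    = sprintf("E%di%d", left_ord, right_ord),
    I_E_AS    = sprintf("i%dE%d", left_ord, right_ord),
    stop("unknown event type: ", type)
  )
}

#' Parse a mode string into an event skeleton
#'
#' Accepts the canonical form (`"i3E4"`, `"E102E182"`) and the
#' underscore-separated variant (`"E7_E11"`). Ordinal digits are consumed
#' greedily up to the next feature letter, so `"E102E182"` is exons 102 and
#' 182, never 10/2.
#'
#' @param s Mode string.
#' @return List with `type`, `left_kind`, `left_ord`, `right_kind`,
#'   `right_ord` (`NA` for single-feature modes).
#' @export
parse_mode <- function(s) {
  m <- regmatches(s, regexec("^([Ei])([0-9]+)(?:_?([Ei])([0-9]+))?$", s))[[1]]
  if (length(m) == 0L) {
    bad <- regmatches(s, regexec("^[Ei][0-9]+_?", s))[[1]]
    offender <- if (length(bad)) substring(s, nchar(bad) + 1L) else s
    stop("unparseable mode string '", s, "' (offending token: '", offender, "')")
  }
  lk <- m[2]; lo <- as.integer(m[3])
  rk <- if (nzchar(m[4])) m[4] else NA_character_
  ro <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
  type <- if (is.na(rk)) {
    if (lk == "E") "EXON_NM" else "INTRON_AS"
  } else if (lk == "E" && rk == "E") {
    if (ro == lo + 1L) "E_E_NM"
    else if (ro >= lo + 2L) "E_E_AS"
    else stop("mode '", s, "': exon-exon join requires right ordinal > left")
  } else if (lk == "E" && rk == "i") {
    if (ro != lo) stop("mode '", s, "': exon-intron join must pair exon k with intron k")
    "E_I_AS"
  } else if (lk == "i" && rk == "E") {
    if (ro != lo + 1L) stop("mode '", s, "': intron-exon join must pair intron k with exon k+1")
    "I_E_AS"
  }
  list(type = type, left_kind = lk, left_ord = lo, right_kind = rk, right_ord = ro)
}

#' Enumerate every elementary splicing event of a transcript
#'
#' For a transcript with `E` exons and `I = E - 1` introns the exhaustive
#' event set is: `E` single-exon (`EXON_NM`), `I` neighboring exon--exon
#' (`E_E_NM`), `I` exon--intron (`E_I_AS`), `I` intron--exon (`I_E_AS`),
#' `I` retained-intron (`INTRON_AS`) and `choose(E, 2) - (E - 1)`
#' non-neighboring exon--exon skips (`E_E_AS`).
#'
#' @param model A `transcript_model`.
#' @return Data frame with one row per event: `transcript_id`, `gene_id`,
#'   `type`, `class`, `left_kind`, `left_ord`, `right_kind`, `right_ord`,
#'   `mode`.
#' @export
enumerate_events <- function(model) {
  E <- nrow(model$exons)
  I <- nrow(model$introns)
  rows <- list()
  add <- function(type, lk, lo, rk = NA_character_, ro = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      transcript_id = model$transcript_id,
      gene_id = model$gene_id,
      type = type,
      class = unname(EVENT_CLASS[type]),
      left_kind = lk, left_ord = lo,
      right_kind = rk, right_ord = ro,
      mode = mode_string(type, lo, ro),
      stringsAsFactors = FALSE
    )
  }
  for (k in seq_len(E)) add("EXON_NM", "E", k)
  for (k in seq_len(I)) add("E_E_NM", "E", k, "E", k + 1L)
  for (k in seq_len(I)) add("E_I_AS", "E", k, "i", k)
  for (k in seq_len(I)) add("I_E_AS", "i", k, "E", k + 1L)
  for (k in seq_len(I)) add("INTRON_AS", "i", k)
  if (E >= 3L) {
    for (a in seq_len(E - 2L)) {
      for (b in seq.int(a + 2L, E)) add("E_E_AS", "E", a, "E", b)
    }
  }
  do.call(rbind, rows)
}

# Effective phase at a 0-based offset s0 into an exon whose annotated phase
# is p: translation starts at (3 - p) %% 3 within the exon, so the frame
# advances with the offset.
effective_phase <- function(phase, s0) {
  if (is.na(phase)) return(NA_integer_)
  as.integer((phase + s0) %% 3L)
}

# Genomic interval of the oriented sub-window [s0+1, s0+len] of a feature.
window_coords <- function(frow, strand, s0, len) {
  if (identical(strand, "-")) {
    c(start = frow$end - s0 - len + 1L, end = frow$end - s0)
  } else {
    c(start = frow$start + s0, end = frow$start + s0 + len - 1L)
  }
}

new_ast <- function(event, sequence, junction_offset, left_truncated,
                    right_truncated, window, n_windows, phase, contig, strand,
                    left_coords, right_coords = NULL) {
  structure(list(
    event = event, sequence = sequence, junction_offset = junction_offset,
    left_truncated = left_truncated, right_truncated = right_truncated,
    window = window, n_windows = n_windows, phase = phase,
    contig = contig, strand = strand,
    left_coords = left_coords, right_coords = right_coords
  ), class = "splice_ast")
}

#' @export
print.splice_ast <- function(x, ...) {
  cat(sprintf("splice_ast %s %s: %d nt%s%s\n", x$event$transcript_id,
              x$event$mode, nchar(x$sequence),
              if (!is.na(x$junction_offset))
                sprintf(", junction at %d", x$junction_offset) else "",
              if (!is.na(x$window)) sprintf(" [window %d/%d]", x$window,
                                            x$n_windows) else ""))
  invisible(x)
}

#' Assemble the artificial splicing transcript(s) of an event
#'
#' Junction events yield one AST: the last `min(flank, |L|)` nt of the left
#' feature joined to the first `min(flank, |R|)` nt of the right feature, in
#' transcript orientation (240 nt total at the default flank when both
#' features are long enough). Flanks are drawn only from the two joined
#' features and truncate at their boundaries. Single-feature events
#' (`EXON_NM`, `INTRON_AS`) emit the whole feature when it fits in
#' `2 * flank`, otherwise a series of `2 * flank` windows tiled with
#' `flank`-length overlap (the last window is anchored to the feature end),
#' each a separate database entry.
#'
#' @param event One-row event data frame from [enumerate_events()].
#' @param genome DNAStringSet.
#' @param model The owning `transcript_model`.
#' @param flank Flank length in nucleotides (default 120, matched to tryptic
#'   peptide length scales).
#' @return List of `splice_ast` objects (length 1 except for tiled long
#'   single features). Each records its junction offset (nt contributed by
#'   the left feature), truncation flags, window index, effective phase at
#'   the window start (when derivable from exon phase) and the genomic
#'   intervals of its parts.
#' @export
assemble_ast <- function(event, genome, model, flank = 120L) {
  stopifnot(flank >= 1L)
  flank <- as.integer(flank)
  single <- is.na(event$right_kind)
  strand <- model$strand
  contig <- model$contig

  fseq <- function(row) feature_seq(genome, contig, row$start, row$end, strand)

  if (!single) {
    lrow <- feature_row(model, event$left_kind, event$left_ord)
    rrow <- feature_row(model, event$right_kind, event$right_ord)
    lseq <- fseq(lrow); rseq <- fseq(rrow)
    llen <- nchar(lseq); rlen <- nchar(rseq)
    fl <- min(flank, llen); fr <- min(flank, rlen)
    seq <- paste0(substring(lseq, llen - fl + 1L, llen), substring(rseq, 1L, fr))
    # phase of the AST start: only derivable when the left feature is an
    # exon with annotated phase
    ph <- if (event$left_kind == "E") {
      effective_phase(lrow$phase, llen - fl)
    } else NA_integer_
    return(list(new_ast(
      event = event, sequence = seq, junction_offset = fl,
      left_truncated = llen < flank, right_truncated = rlen < flank,
      window = NA_integer_, n_windows = 1L, phase = ph,
      contig = contig, strand = strand,
      left_coords = window_coords(lrow, strand, llen - fl, fl),
      right_coords = window_coords(rrow, strand, 0L, fr)
    )))
  }

  frow <- feature_row(model, event$left_kind, event$left_ord)
  s <- fseq(frow)
  len <- nchar(s)
  wlen <- 2L * flank
  if (len <= wlen) {
    starts <- 0L
  } else {
    starts <- seq.int(0L, len - wlen, by = flank)
    if (starts[length(starts)] + wlen < len) starts <- c(starts, len - wlen)
  }
  lapply(seq_along(starts), function(w) {
    s0 <- starts[w]
    this_len <- min(wlen, len - s0)
    ph <- if (event$left_kind == "E") effective_phase(frow$phase, s0) else NA_integer_
    new_ast(
      event = event, sequence = substring(s, s0 + 1L, s0 + this_len),
      junction_offset = NA_integer_,
      left_truncated = FALSE, right_truncated = FALSE,
      window = if (length(starts) > 1L) w else NA_integer_,
      n_windows = length(starts), phase = ph,
      contig = contig, strand = strand,
      left_coords = window_coords(frow, strand, s0, this_len)
    )
  })
}
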