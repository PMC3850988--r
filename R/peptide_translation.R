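# Translation of artificial splicing transcripts into junction peptides.
# Phase-based translation when the reading frame is known from exon phase;
# otherwise three-frame translation keeping the frame whose stop-free
# peptide spanning the splice site is longest.

# Translate every complete codon of `seq` starting at 0-based offset `off`.
# Codons containing anything outside ACGT (e.g. N) become "X"; stops are "*".
codon_translation <- function(seq, off) {
  n <- nchar(seq)
  K <- (n - off) %/% 3L
  if (K < 1L) return(character(0))
  starts <- off + 3L * (seq_len(K) - 1L) + 1L
  codons <- substring(seq, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

# Stop-free runs of an amino-acid vector, as a data frame of [from, to].
stop_free_runs <- function(aa) {
  ok <- !(aa %in% c("*", "X"))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(from = starts[r$values], to = ends[r$values])
}

new_as_peptide <- function(ast, aa, frame, phase_used, jri, shared) {
  seq <- paste(aa, collapse = "")
  pep <- structure(list(
    event = ast$event,
    sequence = seq,
    frame = frame,
    phase_used = phase_used,
    junction_residue_index = jri,
    junction_shared = shared,
    span = nchar(seq)
  ), class = "as_peptide")
  pep$junction_notation <- annotate_junction(pep)
  pep
}

#' @export
print.as_peptide <- function(x, ...) {
  cat(sprintf("as_peptide %s %s frame %d%s: %s\n", x$event$transcript_id,
              x$event$mode, x$frame, if (x$phase_used) " (phase)" else "",
              x$junction_notation))
  invisible(x)
}

# One frame's candidate junction peptide, or NULL when no stop-free segment
# covers the junction (junction events) / the frame yields no residues
# (single-feature events).
frame_candidate <- function(ast, off, phase_used = FALSE) {
  aa <- codon_translation(ast$sequence, off)
  if (length(aa) == 0L) return(NULL)
  runs <- stop_free_runs(aa)
  if (nrow(runs) == 0L) return(NULL)
  J <- ast$junction_offset

  if (is.na(J)) {
    # single-feature event: longest stop-free segment, earliest on ties
    len <- runs$to - runs$from + 1L
    r <- runs[which.max(len), ]
    return(new_as_peptide(ast, aa[r$from:r$to], off, phase_used,
                          NA_integer_, FALSE))
  }

  if (J <= off) return(NULL)                 # no left-side coverage possible
  shared <- ((J - off) %% 3L) != 0L
  if (shared) {
    ks <- (J - off) %/% 3L + 1L              # codon straddling the junction
    if (ks > length(aa)) return(NULL)
    r <- runs[runs$from <= ks & runs$to >= ks, , drop = FALSE]
    if (nrow(r) == 0L || (r$to - r$from + 1L) < 2L) return(NULL)
    new_as_peptide(ast, aa[r$from:r$to], off, phase_used, ks - r$from + 1L, TRUE)
  } else {
    kL <- (J - off) %/% 3L                   # last codon fully left of junction
    if (kL + 1L > length(aa)) return(NULL)
    r <- runs[runs$from <= kL & runs$to >= kL + 1L, , drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    new_as_peptide(ast, aa[r$from:r$to], off, phase_used, kL - r$from + 1L, FALSE)
  }
}

#' Translate an AST in the frame dictated by exon phase
#'
#' Phase `p` means `p` bases of the first codon at the window start were
#' contributed upstream, so translation begins at nucleotide offset
#' `(3 - p) %% 3`. The returned peptide is the maximal stop-free segment
#' covering the junction (junction events) or the longest stop-free segment
#' (single-feature events); `NULL` when none exists.
#'
#' @param ast A `splice_ast`.
#' @param phase Effective phase at the AST start (0, 1 or 2); defaults to
#'   the phase recorded on the AST.
#' @return An `as_peptide` or `NULL`.
#' @export
translate_with_phase <- function(ast, phase = ast$phase) {
  if (is.na(phase)) stop("AST carries no phase; use translate_three_frames()")
  stopifnot(phase %in% 0:2)
  frame_candidate(ast, (3L - as.integer(phase)) %% 3L, phase_used = TRUE)
}

#' All three frame candidates of an AST
#'
#' Computes the candidate junction peptide of every reading frame offset
#' (0, 1, 2) before selection. Elements are `NULL` where a frame yields no
#' stop-free junction-covering segment.
#'
#' @param ast A `splice_ast`.
#' @return List of length 3 (frames 0, 1, 2).
#' @export
three_frame_candidates <- function(ast) {
  lapply(0:2, function(off) frame_candidate(ast, off))
}

#' Three-frame translation with longest-junction-peptide selection
#'
#' Derives one candidate peptide per reading frame and keeps the frame whose
#' peptide mapping across the splice site is longest (for single-feature
#' events, the longest peptide overall). Ties resolve to the lowest frame
#' offset.
#'
#' @param ast A `splice_ast`.
#' @return The selected `as_peptide`, or `NULL` when every frame fails.
#' @export
translate_three_frames <- function(ast) {
  cands <- three_frame_candidates(ast)
  spans <- vapply(cands, function(p) if (is.null(p)) 0L else p$span, integer(1))
  if (all(spans == 0L)) return(NULL)
  cands[[which.max(spans)]]   # which.max takes the first (lowest frame) on ties
}

#' Length of the peptide segment spanning the splice site
#'
#' The residue count of a candidate peptide that covers its junction, and 0
#' for a failed candidate (`NULL`).
#'
#' @param peptide An `as_peptide` or `NULL`.
#' @return Integer.
#' @export
junction_span_length <- function(peptide) {
  if (is.null(peptide)) return(0L)
  peptide$span
}

#' Junction notation of a peptide
#'
#' Inserts `^` between the residues flanking an inter-codon junction, or
#' wraps the residue of a junction-straddling codon in `()`. Single-feature
#' peptides are returned unchanged.
#'
#' @param peptide An `as_peptide`.
#' @return Character scalar, e.g. `"ELAEDGYSGVE^VR"` or `"LISQIVSSIT(A)SLR"`.
#' @export
annotate_junction <- function(peptide) {
  s <- peptide$sequence
  i <- peptide$junction_residue_index
  if (is.null(i) || is.na(i)) return(s)
  if (isTRUE(peptide$junction_shared)) {
    paste0(substring(s, 1L, i - 1L), "(", substring(s, i, i), ")",
           substring(s, i + 1L))
  } else {
    paste0(substring(s, 1L, i), "^", substring(s, i + 1L))
  }
}

#' Strip junction markers from a notation string
#'
#' @param notation Notation with `^` and `()` markers.
#' @return The bare peptide sequence.
#' @export
strip_junction_markers <- function(notation) {
  gsub("[()^]", "", notation)
}
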