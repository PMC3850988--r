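# Gene-set contexts (pathway / disease / drug / organ / custom) and alias
# resolution, used to restrict a build or a marker analysis to a context.

new_gene_set_context <- function(kind, id, name, members) {
  members <- unique(members[nzchar(members)])
  if (length(members) == 0L) stop("gene-set context '", id, "' has no members")
  structure(list(context_kind = kind, context_id = id, context_name = name,
                 members = members), class = "gene_set_context")
}

#' @export
print.gene_set_context <- function(x, ...) {
  cat(sprintf("gene_set_context %s [%s] '%s': %d members\n", x$context_id,
              x$context_kind, x$context_name, length(x$members)))
  invisible(x)
}

#' Load gene-set contexts from GMT or TSV
#'
#' GMT: one set per line, `name<TAB>description<TAB>member...`. TSV: long
#' format with 2 columns (`set_id`, `member`) or 3 columns
#' (`set_id`, `kind`, `member`), no header required unless the first line
#' matches those column names. Duplicate members collapse.
#'
#' @param path File path; format detected from content (GMT when lines have
#'   >= 3 fields and the file ends in .gmt, else long TSV).
#' @param kind Default context kind for files that do not carry one.
#' @return Named list of `gene_set_context` objects.
#' @export
load_gene_sets <- function(path, kind = "custom") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty gene-set file: ", path)
  is_gmt <- grepl("\\.gmt$", path, ignore.case = TRUE)
  out <- list()
  if (is_gmt) {
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 3L) {
        stop("malformed GMT line ", i, " in ", path,
             ": expected name, description and >=1 member")
      }
      ctx <- new_gene_set_context(kind, f[1], f[2], f[-(1:2)])
      out[[ctx$context_id]] <- ctx
    }
  } else {
    f1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    header <- all(tolower(f1) %in% c("set_id", "kind", "member"))
    body <- if (header) lines[-1] else lines
    recs <- lapply(seq_along(body), function(i) {
      f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
      if (!length(f) %in% 2:3) {
        stop("malformed gene-set TSV line ", i + header, " in ", path,
             ": expected 2 or 3 tab-separated fields")
      }
      if (length(f) == 2L) c(f[1], kind, f[2]) else f
    })
    recs <- do.call(rbind, recs)
    for (id in unique(recs[, 1])) {
      sel <- recs[, 1] == id
      out[[id]] <- new_gene_set_context(recs[sel, 2][1], id, id,
                                        recs[sel, 3])
    }
  }
  out
}

#' Load an alias-to-gene id map
#'
#' Two-column TSV (`alias`, `gene_id`), many aliases to one canonical id.
#' Symbols match case-insensitively; canonical ids are also registered as
#' aliases of themselves.
#'
#' @param path TSV path (header optional).
#' @return An `id_map` (named character vector, lower-cased alias ->
#'   canonical id).
#' @export
load_id_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("id map must have 2 columns (alias, gene_id)")
  if (tolower(df[1, 1]) %in% c("alias", "id") ) df <- df[-1, , drop = FALSE]
  map <- stats::setNames(as.character(df[[2]]), tolower(as.character(df[[1]])))
  canon <- unique(as.character(df[[2]]))
  map <- c(map, stats::setNames(canon, tolower(canon)))
  map <- map[!duplicated(names(map))]
  class(map) <- "id_map"
  map
}

#' Resolve heterogeneous identifiers to canonical gene ids
#'
#' Case-insensitive lookup of symbols / transcript ids / protein ids in the
#' alias map. Unresolved ids are reported, never fatal. Resolution is
#' idempotent: canonical ids resolve to themselves.
#'
#' @param raw_ids Character vector of identifiers.
#' @param id_map An `id_map` from [load_id_map()], or `NULL` (identity
#'   mapping).
#' @return List with `resolved` (unique canonical ids) and `unresolved`.
#' @export
resolve_ids <- function(raw_ids, id_map = NULL) {
  raw_ids <- unique(raw_ids[nzchar(raw_ids)])
  if (is.null(id_map)) {
    return(list(resolved = raw_ids, unresolved = character(0)))
  }
  hit <- unclass(id_map)[tolower(raw_ids)]
  list(resolved = unique(unname(hit[!is.na(hit)])),
       unresolved = raw_ids[is.na(hit)])
}

#' Split a delimited id list
#'
#' Accepts comma, semicolon, whitespace or newline delimiters, in any mix.
#'
#' @param s Character scalar or vector.
#' @return Character vector of ids.
#' @export
split_id_list <- function(s) {
  ids <- unlist(strsplit(paste(s, collapse = "\n"), "[,;[:space:]]+"))
  ids[nzchar(ids)]
}
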