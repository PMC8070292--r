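#' Knowledge-triple CSV column order
#'
#' The exact, fixed column order of the knowledge-triple CSV: two entities
#' (original mention, normalized label, entity type each), the relationship
#' id and type, and provenance (document, sentence position, character spans
#' of the source and target mentions).
#'
#' @return Character vector of the twelve column names.
#' @export
triple_columns <- function() {
  c("relationship_id", "relation_type",
    "subject_mention", "subject_label", "subject_type",
    "object_mention", "object_label", "object_type",
    "doc_id", "sentence_position", "source_pos", "target_pos")
}

#' Convert relation mentions into knowledge triples
#'
#' Normalizes both endpoint labels with [normalize_label()] and drops
#' relations whose endpoints collapse to the same preferred label
#' (post-normalization self-loops). Output order follows input order.
#'
#' @param relations data.frame of relations from [extract_relations()] or
#'   [annotate_corpus()].
#' @param syn a [synonym_table()] or `NULL`.
#' @param config a [normalization_config()].
#' @param known additional known labels for the resolvability checks; see
#'   [normalize_label()].
#' @return data.frame of knowledge triples with the [triple_columns()] layout.
#' @export
to_triples <- function(relations, syn = NULL, config = normalization_config(),
                       known = NULL) {
  empty <- stats::setNames(
    data.frame(matrix(character(), nrow = 0, ncol = 12), stringsAsFactors = FALSE),
    triple_columns()
  )
  empty$sentence_position <- integer()
  if (is.null(relations) || nrow(relations) == 0L) return(empty)
  sl <- normalize_label(relations$source_label, syn, config, known)
  ol <- normalize_label(relations$target_label, syn, config, known)
  keep <- sl != ol
  relations <- relations[keep, , drop = FALSE]
  if (!nrow(relations)) return(empty)
  out <- data.frame(
    relationship_id = relations$relation_id,
    relation_type = relations$relation_type,
    subject_mention = relations$source_surface,
    subject_label = sl[keep],
    subject_type = relations$source_type,
    object_mention = relations$target_surface,
    object_label = ol[keep],
    object_type = relations$target_type,
    doc_id = relations$doc_id,
    sentence_position = as.integer(relations$sentence_index),
    source_pos = sprintf("%d:%d", relations$source_start, relations$source_end),
    target_pos = sprintf("%d:%d", relations$target_start, relations$target_end),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write knowledge triples to CSV
#'
#' @param triples data.frame with the [triple_columns()] layout.
#' @param path output path.
#' @export
write_triples_csv <- function(triples, path) {
  cols <- triple_columns()
  if (!all(cols %in% names(triples))) {
    stop("triples lack required columns", call. = FALSE)
  }
  utils::write.csv(triples[, cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read knowledge triples from CSV
#'
#' Validates the header and the field count of every row; a malformed row is
#' reported with its line number.
#'
#' @param path CSV path written by [write_triples_csv()].
#' @return data.frame of knowledge triples.
#' @export
read_triples_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  bad <- which(nf != 12L)
  if (length(bad)) {
    stop(sprintf("malformed triple row at line %d: %d field(s), expected 12",
                 bad[1], nf[bad[1]]), call. = FALSE)
  }
  x <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  if (!identical(names(x), triple_columns())) {
    stop("triple CSV header does not match the required column order",
         call. = FALSE)
  }
  x$sentence_position <- as.integer(x$sentence_position)
  x
}
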