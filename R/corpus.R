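#' Corpus construction
#'
#' A corpus is an ordered collection of documents, each carrying a unique
#' `doc_id`, an integer publication `year`, an optional `title`, an optional
#' `section` label and the document `text`. Documents are kept sorted by
#' `doc_id` so that every downstream stage is deterministic.
#'
#' @param documents data.frame with columns `doc_id`, `year`, `text` and
#'   optionally `title` and `section`. `section`, when present, must be one of
#'   `ABSTRACT`, `INTRODUCTION`, `RESULTS`, `DISCUSSION`, `OTHER` or `NA`.
#' @param year_range two integers giving the plausible range of publication
#'   years; years outside it are rejected.
#' @return An object of class `corpus`.
#' @export
corpus <- function(documents, year_range = c(1900L, 2100L)) {
  if (!is.data.frame(documents)) {
    stop("`documents` must be a data.frame", call. = FALSE)
  }
  if (nrow(documents) == 0L) {
    documents <- data.frame(
      doc_id = character(), year = integer(), title = character(),
      section = character(), text = character(), stringsAsFactors = FALSE
    )
  }
  required <- c("doc_id", "year", "text")
  missing_cols <- setdiff(required, names(documents))
  if (length(missing_cols)) {
    stop("corpus documents lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"title" %in% names(documents)) documents$title <- NA_character_
  if (!"section" %in% names(documents)) documents$section <- NA_character_
  documents <- documents[, c("doc_id", "year", "title", "section", "text")]
  documents$doc_id <- as.character(documents$doc_id)
  documents$text <- as.character(documents$text)
  documents$title <- as.character(documents$title)
  documents$section <- as.character(documents$section)

  if (any(!nzchar(documents$doc_id)) || anyNA(documents$doc_id)) {
    stop("every document needs a non-empty doc_id", call. = FALSE)
  }
  dup <- unique(documents$doc_id[duplicated(documents$doc_id)])
  if (length(dup)) {
    stop("duplicate doc_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  year <- suppressWarnings(as.integer(documents$year))
  bad <- documents$doc_id[is.na(year) | year < year_range[1] | year > year_range[2]]
  if (length(bad)) {
    stop("invalid year for document(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  documents$year <- year
  ok_sections <- c("ABSTRACT", "INTRODUCTION", "RESULTS", "DISCUSSION", "OTHER")
  bad_sec <- !is.na(documents$section) & !documents$section %in% ok_sections
  if (any(bad_sec)) {
    stop("invalid section label(s): ",
         paste(unique(documents$section[bad_sec]), collapse = ", "),
         call. = FALSE)
  }
  documents <- documents[order(documents$doc_id), , drop = FALSE]
  rownames(documents) <- NULL
  structure(list(documents = documents), class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  n <- nrow(x$documents)
  yrs <- if (n) paste(range(x$documents$year), collapse = "-") else "none"
  cat(sprintf("<corpus> %d document(s), years %s\n", n, yrs))
  invisible(x)
}

#' Load a corpus from a directory of text files plus a metadata table
#'
#' Reads all `.txt` files from `text_dir` (one document per file, UTF-8; the
#' doc_id is the file name without the extension) and joins them to a
#' tab-separated metadata table with header columns
#' `doc_id`, `year` and optionally `title`, `section`.
#'
#' @param text_dir directory containing per-document `.txt` files.
#' @param metadata path to the metadata TSV.
#' @inheritParams corpus
#' @return A [corpus].
#' @export
load_corpus <- function(text_dir, metadata, year_range = c(1900L, 2100L)) {
  if (!dir.exists(text_dir)) {
    stop("corpus directory does not exist: ", text_dir, call. = FALSE)
  }
  if (!file.exists(metadata)) {
    stop("metadata file does not exist: ", metadata, call. = FALSE)
  }
  meta <- utils::read.delim(metadata, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "",
                            fileEncoding = "UTF-8")
  if (!all(c("doc_id", "year") %in% names(meta))) {
    stop("metadata must have columns doc_id and year", call. = FALSE)
  }
  dupm <- unique(meta$doc_id[duplicated(meta$doc_id)])
  if (length(dupm)) {
    stop("duplicate doc_id in metadata: ", paste(dupm, collapse = ", "),
         call. = FALSE)
  }
  files <- sort(list.files(text_dir, pattern = "\\.txt$", full.names = TRUE))
  ids <- sub("\\.txt$", "", basename(files))
  missing <- setdiff(ids, meta$doc_id)
  if (length(missing)) {
    stop("no metadata row for document(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  year_num <- suppressWarnings(as.integer(meta$year))
  badyr <- meta$doc_id[is.na(year_num)]
  if (length(badyr)) {
    stop("unparseable year for document(s): ", paste(badyr, collapse = ", "),
         call. = FALSE)
  }
  texts <- vapply(files, function(f) {
    paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  }, character(1))
  meta <- meta[match(ids, meta$doc_id), , drop = FALSE]
  docs <- data.frame(
    doc_id = ids,
    year = year_num[match(ids, meta$doc_id)],
    title = if ("title" %in% names(meta)) meta$title else
      rep(NA_character_, length(ids)),
    section = if ("section" %in% names(meta)) meta$section else
      rep(NA_character_, length(ids)),
    text = unname(texts),
    stringsAsFactors = FALSE
  )
  corpus(docs, year_range = year_range)
}

#' Year index of a corpus
#'
#' @param x a [corpus].
#' @return Named list mapping each year (as character) to the sorted doc_ids
#'   published in that year.
#' @export
year_index <- function(x) {
  stopifnot(inherits(x, "corpus"))
  if (nrow(x$documents) == 0L) return(structure(list(), names = character()))
  lapply(split(x$documents$doc_id, x$documents$year), sort)
}

#' Cumulative year subset of a corpus
#'
#' Returns the sub-corpus of all documents published up to and including
#' `upto_year`, mirroring the cumulative yearly slices used for the
#' time-resolved network series.
#'
#' @param x a [corpus].
#' @param upto_year integer year; documents with `year <= upto_year` are kept.
#' @return A [corpus].
#' @export
subset_by_year <- function(x, upto_year) {
  stopifnot(inherits(x, "corpus"), is.numeric(upto_year), length(upto_year) == 1L)
  corpus(x$documents[x$documents$year <= upto_year, , drop = FALSE])
}

#' Default non-terminal abbreviations for sentence segmentation
#'
#' Tokens after which a period does not end a sentence.
#' @return Character vector.
#' @export
default_abbreviations <- function() {
  c("Fig.", "Figs.", "al.", "e.g.", "i.e.", "spp.", "sp.", "cv.", "cvs.",
    "vs.", "ca.", "approx.", "no.", "No.", "var.")
}

#' Segment a document into sentences
#'
#' Splits on sentence-final punctuation (`.`, `!`, `?`) followed by whitespace
#' and an uppercase letter or digit, except when the token ending in the
#' punctuation is a known non-terminal abbreviation. Offsets are 0-based,
#' half-open character positions into the document text, so
#' `substr(text, start + 1, end)` recovers each sentence.
#'
#' @param doc a single document: either a one-row data.frame with columns
#'   `doc_id` and `text` (e.g. a row of `corpus$documents`) or a list with
#'   those fields.
#' @param abbreviations character vector of non-terminal tokens (compared
#'   case-insensitively); see [default_abbreviations()].
#' @return data.frame with columns `doc_id`, `index` (0-based sentence
#'   position), `start`, `end` (0-based half-open offsets) and `text`.
#' @export
segment_sentences <- function(doc, abbreviations = default_abbreviations()) {
  if (is.data.frame(doc)) {
    stopifnot(nrow(doc) == 1L)
    doc <- as.list(doc)
  }
  doc_id <- as.character(doc$doc_id)
  text <- as.character(doc$text)
  empty <- data.frame(
    doc_id = character(), index = integer(), start = integer(),
    end = integer(), text = character(), stringsAsFactors = FALSE
  )
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  abbr <- tolower(abbreviations)
  # candidate breaks: end of a punctuation run followed by whitespace + [A-Z0-9]
  m <- gregexpr("[.!?]+(?=[[:space:]]+[[:upper:][:digit:]])", text, perl = TRUE)[[1]]
  ends <- integer()
  if (m[1] != -1L) {
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      p <- m[k] + lens[k] - 1L        # 1-based position of last punctuation char
      tok <- sub(".*[[:space:]]", "", substr(text, 1L, p))
      if (!(tolower(tok) %in% abbr)) ends <- c(ends, p)
    }
  }
  bounds <- c(ends, nchar(text))
  sent_start <- integer()
  sent_end <- integer()
  cur <- 1L
  for (b in bounds) {
    if (b < cur) next
    chunk <- substr(text, cur, b)
    # leading whitespace is attributed to the inter-sentence gap
    lead <- attr(regexpr("^[[:space:]]*", chunk), "match.length")
    s <- cur + lead
    e <- b
    while (e >= s && grepl("[[:space:]]", substr(text, e, e))) e <- e - 1L
    if (e >= s) {
      sent_start <- c(sent_start, s)
      sent_end <- c(sent_end, e)
    }
    cur <- b + 1L
  }
  if (!length(sent_start)) return(empty)
  data.frame(
    doc_id = doc_id,
    index = seq_along(sent_start) - 1L,
    start = sent_start - 1L,
    end = sent_end,                      # half-open: (start0, end0]
    text = substring(text, sent_start, sent_end),
    stringsAsFactors = FALSE
  )
}

#' Write sentences to a TSV file
#'
#' @param sentences data.frame from [segment_sentences()].
#' @param path output path.
#' @export
write_sentences_tsv <- function(sentences, path) {
  utils::write.table(
    sentences[, c("doc_id", "index", "start", "end", "text")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}
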