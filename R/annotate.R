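#' The entity type system
#'
#' The closed set of entity classes the annotator may emit: genes and proteins
#' are deliberately merged into a single class (they are used interchangeably
#' in the literature), metabolites and traits are the other two.
#'
#' @return Character vector of the three entity type names.
#' @export
entity_types <- function() c("GENE_PROTEIN", "METABOLITE", "TRAIT")

#' The relation type registry
#'
#' The registry contains exactly seven relation types. `RELATED_TO` is the
#' generic, all-encompassing association label and is always present;
#' `ENCODES` and `PART_OF` are the two specific types that occur often enough
#' in the domain to be worth distinguishing. The remaining four slots are
#' configurable placeholders that never fire unless trigger keywords are
#' mapped to them.
#'
#' @param generic character vector of exactly four additional registry names.
#' @return Character vector of seven relation type names.
#' @export
relation_registry <- function(generic = paste0("GENERIC_", 1:4)) {
  if (length(generic) != 4L || anyDuplicated(generic)) {
    stop("the registry needs exactly 4 distinct generic relation names",
         call. = FALSE)
  }
  reg <- c("RELATED_TO", "ENCODES", "PART_OF", as.character(generic))
  if (anyDuplicated(reg)) stop("relation registry names must be distinct",
                               call. = FALSE)
  reg
}

#' Build a lexicon from a data.frame
#'
#' A lexicon maps case-folded surface forms to a preferred label and an
#' entity type. Multiple surfaces may share a preferred label (spelling
#' variants), but no surface may map to two different types or labels.
#'
#' @param entries data.frame with columns `surface`, `preferred_label`,
#'   `entity_type`.
#' @return Object of class `lexicon`: a data.frame with case-folded, unique
#'   `surface` keys.
#' @export
lexicon <- function(entries) {
  stopifnot(is.data.frame(entries))
  need <- c("surface", "preferred_label", "entity_type")
  if (!all(need %in% names(entries))) {
    stop("lexicon needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  entries <- entries[, need]
  entries$surface <- tolower(trimws(as.character(entries$surface)))
  entries$preferred_label <- as.character(entries$preferred_label)
  entries$entity_type <- as.character(entries$entity_type)
  if (any(!nzchar(entries$surface))) {
    stop("lexicon contains an empty surface form", call. = FALSE)
  }
  bad <- setdiff(unique(entries$entity_type), entity_types())
  if (length(bad)) {
    stop("invalid entity type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  entries <- unique(entries)
  dup <- entries$surface[duplicated(entries$surface)]
  if (length(dup)) {
    rows <- entries[entries$surface %in% dup, ]
    stop("conflicting lexicon entries for surface(s): ",
         paste(unique(sprintf("'%s' (%s)", rows$surface, rows$entity_type)),
               collapse = ", "), call. = FALSE)
  }
  entries <- entries[order(entries$surface), , drop = FALSE]
  rownames(entries) <- NULL
  class(entries) <- c("lexicon", "data.frame")
  entries
}

#' Load a lexicon from one or more TSV files
#'
#' Each file is tab-separated with header `surface`, `preferred_label`,
#' `entity_type` (`GENE_PROTEIN`, `METABOLITE` or `TRAIT`).
#'
#' @param paths character vector of TSV paths.
#' @return A [lexicon].
#' @export
load_lexicon <- function(paths) {
  tabs <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("lexicon file does not exist: ", p, call. = FALSE)
    utils::read.delim(p, sep = "\t", header = TRUE, colClasses = "character",
                      quote = "", fileEncoding = "UTF-8")
  })
  lexicon(do.call(rbind, tabs))
}

#' Load relation trigger keywords
#'
#' Tab-separated file with header `keyword`, `relation_type`. A trigger
#' keyword occurring between two entity mentions upgrades the relation label
#' from the generic `RELATED_TO` to the mapped type.
#'
#' @param path TSV path.
#' @param registry relation registry the types must belong to.
#' @return data.frame with columns `keyword`, `relation_type`.
#' @export
load_triggers <- function(path, registry = relation_registry()) {
  tr <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  triggers(tr, registry = registry)
}

#' @rdname load_triggers
#' @param entries data.frame with columns `keyword`, `relation_type`.
#' @export
triggers <- function(entries, registry = relation_registry()) {
  stopifnot(is.data.frame(entries))
  if (!all(c("keyword", "relation_type") %in% names(entries))) {
    stop("triggers need columns keyword and relation_type", call. = FALSE)
  }
  entries <- entries[, c("keyword", "relation_type")]
  bad <- setdiff(unique(entries$relation_type), registry)
  if (length(bad)) {
    stop("trigger relation type(s) not in registry: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  entries
}

# TRUE where the character at 1-based position i of `text` is part of a token.
# Tokens are runs of alphanumerics plus internal hyphens and apostrophes, so
# hyphen-rich metabolite names ("lutein-5,6-epoxide") stay single units and
# "carotene" does not match inside "beta-carotene-like".
is_token_char <- function(text, i) {
  if (i < 1L || i > nchar(text)) return(FALSE)
  grepl("[[:alnum:]'’-]", substr(text, i, i))
}

#' Find dictionary entity mentions in a sentence
#'
#' Case-insensitive, token-boundary dictionary matching. Among overlapping
#' candidate matches the leftmost match wins, and among candidates starting at
#' the same position the longest wins; the returned mentions are
#' non-overlapping and ordered by start offset.
#'
#' @param sentence one sentence: a one-row data.frame (as produced by
#'   [segment_sentences()]) or list with fields `doc_id`, `index`, `text`.
#' @param lex a [lexicon].
#' @return data.frame with columns `doc_id`, `sentence_index`, `start`, `end`
#'   (0-based half-open offsets within the sentence), `surface` (matched
#'   text as it appears), `entity_type`, `preferred_label`.
#' @export
find_mentions <- function(sentence, lex) {
  stopifnot(inherits(lex, "lexicon"))
  if (is.data.frame(sentence)) {
    stopifnot(nrow(sentence) == 1L)
    sentence <- as.list(sentence)
  }
  text <- as.character(sentence$text)
  low <- tolower(text)
  empty <- data.frame(
    doc_id = character(), sentence_index = integer(), start = integer(),
    end = integer(), surface = character(), entity_type = character(),
    preferred_label = character(), stringsAsFactors = FALSE
  )
  if (!nzchar(low)) return(empty)

  cand <- vector("list", nrow(lex))
  for (k in seq_len(nrow(lex))) {
    s <- lex$surface[k]
    hits <- gregexpr(s, low, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    len <- nchar(s)
    ok <- vapply(hits, function(p) {
      !is_token_char(low, p - 1L) && !is_token_char(low, p + len)
    }, logical(1))
    if (!any(ok)) next
    cand[[k]] <- data.frame(
      pos = as.integer(hits[ok]), len = len, row = k, stringsAsFactors = FALSE
    )
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L) return(empty)

  cand <- cand[order(cand$pos, -cand$len), , drop = FALSE]
  keep <- logical(nrow(cand))
  cur_end <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cand$pos[i] > cur_end) {
      keep[i] <- TRUE
      cur_end <- cand$pos[i] + cand$len[i] - 1L
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(
    doc_id = as.character(sentence$doc_id),
    sentence_index = as.integer(sentence$index),
    start = cand$pos - 1L,
    end = cand$pos - 1L + cand$len,
    surface = substring(text, cand$pos, cand$pos + cand$len - 1L),
    entity_type = lex$entity_type[cand$row],
    preferred_label = lex$preferred_label[cand$row],
    stringsAsFactors = FALSE
  )
}

#' Extract within-sentence relations between entity mentions
#'
#' Emits one relation per unordered pair of mentions with distinct preferred
#' labels (all-pairs co-occurrence). If a trigger keyword occurs in the text
#' between the two mention spans the relation takes the trigger's type,
#' otherwise the generic `RELATED_TO`. Relations never cross sentence
#' boundaries; pairs whose mentions share a preferred label are suppressed
#' (no self-loops).
#'
#' @param mentions data.frame of mentions from [find_mentions()], all from the
#'   same document and sentence.
#' @param sentence the sentence the mentions belong to (for the inter-mention
#'   text used in trigger search).
#' @param trig optional trigger table from [triggers()]; `NULL` means every
#'   relation is `RELATED_TO`.
#' @return data.frame with one row per relation: `relation_id`,
#'   `relation_type`, `doc_id`, `sentence_index`, and `source_*` / `target_*`
#'   columns (`surface`, `label`, `type`, `start`, `end`).
#' @export
extract_relations <- function(mentions, sentence, trig = NULL) {
  empty <- data.frame(
    relation_id = character(), relation_type = character(),
    doc_id = character(), sentence_index = integer(),
    source_surface = character(), source_label = character(),
    source_type = character(), source_start = integer(), source_end = integer(),
    target_surface = character(), target_label = character(),
    target_type = character(), target_start = integer(), target_end = integer(),
    stringsAsFactors = FALSE
  )
  if (is.null(mentions) || nrow(mentions) < 2L) return(empty)
  if (length(unique(mentions$doc_id)) > 1L ||
      length(unique(mentions$sentence_index)) > 1L) {
    stop("mentions must all come from a single sentence", call. = FALSE)
  }
  if (is.data.frame(sentence)) {
    stopifnot(nrow(sentence) == 1L)
    sentence <- as.list(sentence)
  }
  text <- as.character(sentence$text)
  mentions <- mentions[order(mentions$start), , drop = FALSE]
  n <- nrow(mentions)
  out <- list()
  ord <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (mentions$preferred_label[i] == mentions$preferred_label[j]) next
      rtype <- "RELATED_TO"
      if (!is.null(trig) && nrow(trig)) {
        between <- substr(text, mentions$end[i] + 1L, mentions$start[j])
        best <- Inf
        for (t in seq_len(nrow(trig))) {
          pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                    trig$keyword[t]), "\\b")
          hit <- regexpr(pat, between, ignore.case = TRUE, perl = TRUE)
          if (hit[1] != -1L && hit[1] < best) {
            best <- hit[1]
            rtype <- trig$relation_type[t]
          }
        }
      }
      ord <- ord + 1L
      out[[ord]] <- data.frame(
        relation_id = sprintf("%s.s%d.r%d", mentions$doc_id[i],
                              mentions$sentence_index[i], ord),
        relation_type = rtype,
        doc_id = mentions$doc_id[i],
        sentence_index = mentions$sentence_index[i],
        source_surface = mentions$surface[i],
        source_label = mentions$preferred_label[i],
        source_type = mentions$entity_type[i],
        source_start = mentions$start[i],
        source_end = mentions$end[i],
        target_surface = mentions$surface[j],
        target_label = mentions$preferred_label[j],
        target_type = mentions$entity_type[j],
        target_start = mentions$start[j],
        target_end = mentions$end[j],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate a whole corpus
#'
#' Runs sentence segmentation, dictionary NER and within-sentence relation
#' extraction over every document, concatenating results in corpus (doc_id)
#' order. Mentions that take part in no relation are retained in the mention
#' list; they simply never reach the network stage.
#'
#' @param x a [corpus].
#' @param lex a [lexicon].
#' @param trig optional trigger table; see [extract_relations()].
#' @param abbreviations passed to [segment_sentences()].
#' @return Object of class `annotation_set`: list with data.frames
#'   `sentences`, `mentions`, `relations`.
#' @export
annotate_corpus <- function(x, lex, trig = NULL,
                            abbreviations = default_abbreviations()) {
  stopifnot(inherits(x, "corpus"))
  sent_l <- list(); men_l <- list(); rel_l <- list()
  for (d in seq_len(nrow(x$documents))) {
    doc <- x$documents[d, , drop = FALSE]
    sents <- segment_sentences(doc, abbreviations = abbreviations)
    sent_l[[length(sent_l) + 1L]] <- sents
    for (s in seq_len(nrow(sents))) {
      sen <- sents[s, , drop = FALSE]
      m <- find_mentions(sen, lex)
      if (nrow(m)) {
        men_l[[length(men_l) + 1L]] <- m
        r <- extract_relations(m, sen, trig = trig)
        if (nrow(r)) rel_l[[length(rel_l) + 1L]] <- r
      }
    }
  }
  bind <- function(l, proto) {
    if (length(l)) {
      out <- do.call(rbind, l); rownames(out) <- NULL; out
    } else proto
  }
  structure(list(
    sentences = bind(sent_l, segment_sentences(list(doc_id = "", text = ""))),
    mentions = bind(men_l, find_mentions(list(doc_id = "", index = 0L, text = ""),
                                         lex)),
    relations = bind(rel_l, extract_relations(NULL, NULL))
  ), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d sentence(s), %d mention(s), %d relation(s)\n",
              nrow(x$sentences), nrow(x$mentions), nrow(x$relations)))
  invisible(x)
}

#' Write mentions or relations to TSV
#'
#' @param x data.frame of mentions or relations.
#' @param path output path.
#' @export
write_annotations_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
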