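# Independent test oracles. These deliberately avoid the package's code paths
# (igraph, gregexpr-based matching) so that agreement is informative.

# Brute-force BFS: shortest unweighted distance between two labels over an
# edge list; Inf if unreachable or either endpoint absent.
oracle_bfs <- function(edges, from, to) {
  nodes <- unique(c(edges$source, edges$target))
  if (!(from %in% nodes) || !(to %in% nodes)) return(Inf)
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    nb <- c(edges$target[edges$source == u], edges$source[edges$target == u])
    for (w in nb) {
      if (dist[w] > dist[u] + 1) {
        dist[w] <- dist[u] + 1
        queue <- c(queue, w)
      }
    }
  }
  unname(dist[to])
}

oracle_dist_to_set <- function(edges, from, to_set) {
  d <- suppressWarnings(min(vapply(to_set, function(t) oracle_bfs(edges, from, t),
                                   numeric(1))))
  d
}

# Character-by-character dictionary matcher: enumerate every candidate match
# of every surface at every position (own boundary test), then apply the
# leftmost-longest rule by explicit sorting and greedy selection.
oracle_find_mentions <- function(text, lex) {
  low <- tolower(text)
  n <- nchar(low)
  token_char <- function(i) {
    if (i < 1 || i > n) return(FALSE)
    ch <- substr(low, i, i)
    grepl("[[:alnum:]'’-]", ch)
  }
  cand <- list()
  for (k in seq_len(nrow(lex))) {
    s <- lex$surface[k]
    len <- nchar(s)
    if (len > n) next
    for (p in seq_len(n - len + 1)) {
      if (substr(low, p, p + len - 1) == s &&
          !token_char(p - 1) && !token_char(p + len)) {
        cand[[length(cand) + 1]] <- data.frame(pos = p, len = len, row = k)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(), end = integer(),
                      preferred_label = character()))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$pos, -cand$len), , drop = FALSE]
  keep <- logical(nrow(cand)); cur_end <- 0
  for (i in seq_len(nrow(cand))) {
    if (cand$pos[i] > cur_end) {
      keep[i] <- TRUE
      cur_end <- cand$pos[i] + cand$len[i] - 1
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(start = cand$pos - 1L, end = cand$pos - 1L + cand$len,
             preferred_label = lex$preferred_label[cand$row])
}

# Random triple sets over a small label universe, with consistent entity
# types, for network-invariant property tests.
random_triples <- function(n_labels = 10, n_triples = 20, n_docs = 5) {
  labels <- sprintf("NODE%02d", seq_len(n_labels))
  types <- sample(entity_types(), n_labels, replace = TRUE)
  names(types) <- labels
  pair <- t(replicate(n_triples, sample(labels, 2)))
  data.frame(
    relationship_id = sprintf("r%d", seq_len(n_triples)),
    relation_type = "RELATED_TO",
    subject_mention = pair[, 1], subject_label = pair[, 1],
    subject_type = unname(types[pair[, 1]]),
    object_mention = pair[, 2], object_label = pair[, 2],
    object_type = unname(types[pair[, 2]]),
    doc_id = sample(sprintf("D%d", seq_len(n_docs)), n_triples, replace = TRUE),
    sentence_position = 0L,
    source_pos = "0:1", target_pos = "2:3",
    stringsAsFactors = FALSE
  )
}

# Random planted schedules over the generator vocabulary: a chain of events
# that eventually reaches a flesh node, plus unconstrained extra events.
random_schedule <- function(year_min = 2000, span = 5) {
  voc <- synth_vocabulary()
  canon <- names(voc)
  traits <- canon[vapply(voc, function(v) v$entity_type == "TRAIT", logical(1))]
  non_traits <- setdiff(canon, traits)
  flesh <- sample(traits, sample(1:2, 1))
  years <- seq(year_min, year_min + span - 1)
  chain_len <- sample(2:4, 1)
  chain <- c(sample(non_traits, chain_len), sample(flesh, 1))
  chain_years <- sort(sample(years, chain_len, replace = TRUE))
  events <- data.frame(
    year = chain_years,
    subject_label = chain[seq_len(chain_len)],
    relation_type = "RELATED_TO",
    object_label = chain[seq_len(chain_len) + 1],
    stringsAsFactors = FALSE
  )
  n_extra <- sample(0:3, 1)
  for (k in seq_len(n_extra)) {
    pair <- sample(canon, 2)
    events <- rbind(events, data.frame(
      year = sample(years, 1), subject_label = pair[1],
      relation_type = sample(c("RELATED_TO", "ENCODES", "PART_OF"), 1),
      object_label = pair[2], stringsAsFactors = FALSE
    ))
  }
  planted_schedule(events, flesh)
}

# Toy lexicon used across annotation tests.
toy_lexicon <- function() {
  lexicon(data.frame(
    surface = c("zeaxanthin epoxidase", "zeaxanthin", "zep", "color",
                "flesh color", "beta-carotene", "carotene"),
    preferred_label = c("ZEAXANTHIN EPOXIDASE", "ZEAXANTHIN",
                        "ZEAXANTHIN EPOXIDASE", "COLOR", "FLESH COLOR",
                        "BETA-CAROTENE", "CAROTENE"),
    entity_type = c("GENE_PROTEIN", "METABOLITE", "GENE_PROTEIN", "TRAIT",
                    "TRAIT", "METABOLITE", "METABOLITE"),
    stringsAsFactors = FALSE
  ))
}

make_sentence <- function(text, doc_id = "doc1", index = 0L) {
  list(doc_id = doc_id, index = index, text = text)
}

# Write a corpus directory + metadata TSV under a temp dir.
write_corpus_dir <- function(texts, years, sections = NULL) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  txt <- file.path(dir, "corpus")
  dir.create(txt)
  for (id in names(texts)) {
    writeLines(texts[[id]], file.path(txt, paste0(id, ".txt")))
  }
  meta <- data.frame(doc_id = names(texts), year = years,
                     stringsAsFactors = FALSE)
  if (!is.null(sections)) meta$section <- sections
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(dir = txt, metadata = file.path(dir, "metadata.tsv"))
}
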