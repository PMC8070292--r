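#' Built-in vocabulary of the synthetic-corpus generator
#'
#' Each canonical (normalized) label carries an entity type and one or more
#' surface variants. Variants deliberately include normalization stressors —
#' species prefixes (`StZEP`, `StAN1`), gene-family digits (`BCH1`, `PSY1`),
#' abbreviations (`ZEP`, `ABA`, `NCED2`), Greek letters and British spellings
#' — so that generated corpora exercise the normalization rules end-to-end.
#' Every variant's lexicon label normalizes to the canonical label under
#' [synth_normalization_config()] and [synth_synonyms()].
#'
#' @return Named list: canonical label -> list(entity_type, variants
#'   data.frame with `surface`, `label`).
#' @export
synth_vocabulary <- function() {
  v <- function(type, ...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    list(entity_type = type,
         variants = data.frame(surface = m[, 1], label = m[, 2],
                               stringsAsFactors = FALSE))
  }
  list(
    "ZEAXANTHIN EPOXIDASE" = v("GENE_PROTEIN",
      "zeaxanthin epoxidase", "ZEAXANTHIN EPOXIDASE",
      "ZEP", "ZEP",
      "StZEP", "StZEP"),
    "BETA-CAROTENE HYDROXYLASE" = v("GENE_PROTEIN",
      "beta-carotene hydroxylase", "BETA-CAROTENE HYDROXYLASE",
      "BCH1", "BCH1",
      "BCH2", "BCH2"),
    "PHYTOENE SYNTHASE" = v("GENE_PROTEIN",
      "phytoene synthase", "PHYTOENE SYNTHASE",
      "PSY1", "PSY1"),
    "AN1" = v("GENE_PROTEIN",
      "AN1", "AN1",
      "StAN1", "StAN1"),
    "9-CIS-EPOXYCAROTENOID DIOXYGENASE" = v("GENE_PROTEIN",
      "9-cis-epoxycarotenoid dioxygenase", "9-CIS-EPOXYCAROTENOID DIOXYGENASE",
      "NCED2", "NCED2"),
    "LYCOPENE E-CYCLASE" = v("GENE_PROTEIN",
      "lycopene e-cyclase", "LYCOPENE E-CYCLASE"),
    "BHLH" = v("GENE_PROTEIN", "bHLH", "BHLH"),
    "BETA-CAROTENE" = v("METABOLITE",
      "beta-carotene", "BETA-CAROTENE",
      "b-carotene", "B-CAROTENE",
      "β-carotene", "β-carotene"),
    "ZEAXANTHIN" = v("METABOLITE", "zeaxanthin", "ZEAXANTHIN"),
    "VIOLAXANTHIN" = v("METABOLITE", "violaxanthin", "VIOLAXANTHIN"),
    "LUTEIN" = v("METABOLITE", "lutein", "LUTEIN"),
    "CAROTENOID" = v("METABOLITE",
      "carotenoid", "CAROTENOID",
      "carotenoids", "carotenoids"),
    "ANTHOCYANIN" = v("METABOLITE", "anthocyanin", "ANTHOCYANIN"),
    "ABSCISIC ACID" = v("METABOLITE",
      "abscisic acid", "ABSCISIC ACID",
      "ABA", "ABA"),
    "FLESH COLOR" = v("TRAIT",
      "flesh color", "FLESH COLOR",
      "flesh colour", "flesh colour"),
    "TUBER FLESH COLOR" = v("TRAIT", "tuber flesh color", "TUBER FLESH COLOR"),
    "TUBER COLOR" = v("TRAIT", "tuber color", "TUBER COLOR"),
    "ORANGE FLESH COLOR" = v("TRAIT",
      "orange flesh color", "ORANGE FLESH COLOR")
  )
}

#' Lexicon of the synthetic-corpus generator
#'
#' One entry per surface variant in [synth_vocabulary()]; the preferred label
#' of each entry is the variant form itself (short gene symbols, prefixed
#' forms), which the normalization stage later maps onto the canonical label.
#'
#' @return A [lexicon].
#' @export
synth_lexicon <- function() {
  voc <- synth_vocabulary()
  rows <- lapply(names(voc), function(canon) {
    data.frame(surface = voc[[canon]]$variants$surface,
               preferred_label = voc[[canon]]$variants$label,
               entity_type = voc[[canon]]$entity_type,
               stringsAsFactors = FALSE)
  })
  lexicon(do.call(rbind, rows))
}

#' Synonym table of the synthetic-corpus generator
#'
#' @return A [synonym_table()] resolving every vocabulary variant onto its
#'   canonical label.
#' @export
synth_synonyms <- function() {
  canon <- names(synth_vocabulary())
  self <- data.frame(alias = canon, preferred_label = canon,
                     source = "synthetic", stringsAsFactors = FALSE)
  extra <- data.frame(
    alias = c("ZEP", "BCH", "PSY", "NCED", "B-CAROTENE", "CAROTENOIDS", "ABA"),
    preferred_label = c("ZEAXANTHIN EPOXIDASE", "BETA-CAROTENE HYDROXYLASE",
                        "PHYTOENE SYNTHASE",
                        "9-CIS-EPOXYCAROTENOID DIOXYGENASE", "BETA-CAROTENE",
                        "CAROTENOID", "ABSCISIC ACID"),
    source = "synthetic", stringsAsFactors = FALSE
  )
  synonym_table(rbind(self, extra[!extra$alias %in% canon, ]))
}

#' Normalization configuration of the synthetic-corpus generator
#'
#' @return A [normalization_config()] with the British-spelling map used by
#'   the vocabulary stressors.
#' @export
synth_normalization_config <- function() {
  normalization_config(
    spelling_map = data.frame(variant = "colour", american = "color",
                              stringsAsFactors = FALSE)
  )
}

#' Trigger keywords of the synthetic-corpus generator
#'
#' @return Trigger table mapping `encodes` and `part of` onto their relation
#'   types.
#' @export
synth_triggers <- function() {
  triggers(data.frame(
    keyword = c("encodes", "part of"),
    relation_type = c("ENCODES", "PART_OF"),
    stringsAsFactors = FALSE
  ))
}

#' Sentence templates of the synthetic-corpus generator
#'
#' Two-slot templates (`{A}`, `{B}`) realize planted relations within a
#' single sentence; the template pool is keyed by relation type so that
#' trigger keywords appear exactly when the planted relation calls for them.
#' One-slot templates (`{X}`) and plain sentences serve as distractors and
#' carry at most one lexicon entity, so they never create relations. All
#' templates start with an uppercase word and end in a period so generated
#' documents re-segment cleanly.
#'
#' @return List with elements `relation` (named list: relation type ->
#'   character vector of two-slot templates), `single` and `plain`.
#' @export
default_templates <- function() {
  list(
    relation = list(
      RELATED_TO = c(
        "Recent mapping experiments showed that {A} is closely associated with {B} in potato tubers.",
        "Quantitative analyses revealed a strong link between {A} and {B} across cultivars.",
        "Variation in {A} co-segregated with {B} in the mapping population."
      ),
      ENCODES = c(
        "Sequencing confirmed that {A} encodes {B} in this cultivar."
      ),
      PART_OF = c(
        "Biochemical assays indicated that {A} is part of {B} metabolism."
      )
    ),
    single = c(
      "Expression of {X} was quantified in all genotypes.",
      "Seasonal variation strongly affected the accumulation of {X}."
    ),
    plain = c(
      "Field trials were conducted over three consecutive seasons.",
      "Plants were grown under standard glasshouse conditions.",
      "Tubers were harvested at full maturity and stored at low temperature."
    )
  )
}

#' Configuration of the synthetic-corpus generator
#'
#' The defaults emulate the study conditions of the emulated corpus: yearly
#' batches of abstracts spanning 2000-2016, a few documents per year, a small
#' number of distractor sentences per document and no off-schedule noise.
#'
#' @param years integer vector of corpus years.
#' @param docs_per_year documents generated per year.
#' @param distractor_sentences_per_doc distractor sentences added to each
#'   document (each containing at most one entity).
#' @param noise_rate probability, per document, of one additional
#'   off-schedule random relation sentence.
#' @param seed integer random seed; identical seed and configuration give
#'   byte-identical corpora.
#' @param templates template set; see [default_templates()].
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(years = 2000:2016, docs_per_year = 3L,
                             distractor_sentences_per_doc = 2L,
                             noise_rate = 0, seed = 1L,
                             templates = default_templates()) {
  stopifnot(noise_rate >= 0, noise_rate <= 1, docs_per_year >= 0L)
  for (pool in templates$relation) {
    ok <- grepl("{A}", pool, fixed = TRUE) & grepl("{B}", pool, fixed = TRUE)
    if (!all(ok)) {
      stop("two-slot template lacking {A} and {B}: ", pool[!ok][1],
           call. = FALSE)
    }
  }
  structure(list(
    years = as.integer(years),
    docs_per_year = as.integer(docs_per_year),
    distractor_sentences_per_doc = as.integer(distractor_sentences_per_doc),
    noise_rate = noise_rate,
    seed = as.integer(seed),
    templates = templates
  ), class = "generator_config")
}

#' Planted relation schedule
#'
#' The ground truth of a synthetic corpus: which entity pair becomes related
#' in which year, plus the designated flesh (trait) node set.
#'
#' @param events data.frame with columns `year`, `subject_label`,
#'   `relation_type`, `object_label`; labels are canonical labels from
#'   [synth_vocabulary()].
#' @param flesh_labels non-empty character vector of canonical trait labels.
#' @return Object of class `planted_schedule`.
#' @export
planted_schedule <- function(events, flesh_labels) {
  stopifnot(is.data.frame(events), length(flesh_labels) >= 1L)
  need <- c("year", "subject_label", "relation_type", "object_label")
  if (!all(need %in% names(events))) {
    stop("schedule events need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  events <- events[, need]
  events$year <- as.integer(events$year)
  voc <- names(synth_vocabulary())
  unknown <- setdiff(c(events$subject_label, events$object_label,
                       flesh_labels), voc)
  if (length(unknown)) {
    stop("schedule label(s) not in the generator vocabulary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(events$subject_label == events$object_label)) {
    stop("schedule contains a self-relation", call. = FALSE)
  }
  structure(list(events = events, flesh_labels = as.character(flesh_labels)),
            class = "planted_schedule")
}

#' Read a planted schedule from TSV
#'
#' Tab-separated with header `year`, `subject_label`, `relation_type`,
#' `object_label`; flesh labels are supplied separately.
#'
#' @param path TSV path.
#' @param flesh_labels canonical trait labels.
#' @return A [planted_schedule()].
#' @export
load_schedule <- function(path, flesh_labels) {
  ev <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          fileEncoding = "UTF-8")
  planted_schedule(ev, flesh_labels)
}

# Fill a "{A} ... {B}" or "{X}" template, returning the sentence text and the
# 0-based half-open span of each filled slot.
fill_template <- function(tpl, fillers) {
  text <- ""
  spans <- list()
  rest <- tpl
  repeat {
    m <- regexpr("\\{[ABX]\\}", rest)
    if (m[1] == -1L) {
      text <- paste0(text, rest)
      break
    }
    slot <- substr(rest, m[1] + 1L, m[1] + 1L)
    text <- paste0(text, substr(rest, 1L, m[1] - 1L))
    filler <- fillers[[slot]]
    spans[[slot]] <- c(start = nchar(text), end = nchar(text) + nchar(filler))
    text <- paste0(text, filler)
    rest <- substr(rest, m[1] + attr(m, "match.length"), nchar(rest))
  }
  list(text = text, spans = spans)
}

#' Generate a synthetic corpus with planted relations
#'
#' Produces yearly batches of synthetic documents in which each scheduled
#' relation is realized by at least one template sentence in a document of
#' its year, padded with distractor sentences that contain at most one
#' entity. Gold entity mentions and gold relations are recorded during
#' construction (not by running the annotator), and the expected distance
#' table is computed by the independent breadth-first-search oracle
#' [expected_distances()] on the planted edge schedule.
#'
#' @param config a [generator_config()].
#' @param schedule a [planted_schedule()].
#' @return Object of class `synthetic_bundle`: list with `corpus`,
#'   `gold_mentions`, `gold_relations`, `expected_table`, `schedule`,
#'   `config`, plus the matching `lexicon`, `synonyms`, `triggers` and
#'   `norm_config`.
#' @export
generate <- function(config, schedule) {
  stopifnot(inherits(config, "generator_config"),
            inherits(schedule, "planted_schedule"))
  if (!all(schedule$events$year %in% config$years)) {
    stop("schedule event year(s) outside the configured year range",
         call. = FALSE)
  }
  bad_rel <- setdiff(unique(schedule$events$relation_type),
                     names(config$templates$relation))
  if (length(bad_rel)) {
    stop("no template pool for relation type(s): ",
         paste(bad_rel, collapse = ", "), call. = FALSE)
  }
  voc <- synth_vocabulary()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  pick <- function(x) if (length(x) == 1L) x else sample(x, 1L)
  pick_variant <- function(canon) {
    v <- voc[[canon]]$variants
    i <- if (nrow(v) == 1L) 1L else sample(nrow(v), 1L)
    list(surface = v$surface[i], label = v$label[i],
         entity_type = voc[[canon]]$entity_type)
  }

  docs <- list(); gold_m <- list(); gold_r <- list()
  for (y in config$years) {
    ev_y <- schedule$events[schedule$events$year == y, , drop = FALSE]
    n_docs <- max(config$docs_per_year, if (nrow(ev_y)) 1L else 0L)
    if (n_docs == 0L) next
    assignment <- if (nrow(ev_y)) rep_len(seq_len(n_docs), nrow(ev_y)) else integer()
    for (d in seq_len(n_docs)) {
      doc_id <- sprintf("SYN%d_%02d", y, d)
      sentences <- character()
      add_sentence <- function(res, entities, relation = NULL) {
        idx <- length(sentences)  # 0-based index of the sentence being added
        sentences[[length(sentences) + 1L]] <<- res$text
        for (e in entities) {
          gold_m[[length(gold_m) + 1L]] <<- data.frame(
            doc_id = doc_id, sentence_index = idx,
            start = unname(res$spans[[e$slot]]["start"]),
            end = unname(res$spans[[e$slot]]["end"]),
            surface = e$surface, entity_type = e$entity_type,
            preferred_label = e$label, stringsAsFactors = FALSE
          )
        }
        if (!is.null(relation)) {
          gold_r[[length(gold_r) + 1L]] <<- data.frame(
            doc_id = doc_id, sentence_index = idx,
            relation_type = relation$type,
            source_canonical = relation$subject,
            target_canonical = relation$object,
            planted = relation$planted, stringsAsFactors = FALSE
          )
        }
      }
      add_relation_sentence <- function(subject, rtype, object, planted) {
        tpl <- pick(config$templates$relation[[rtype]])
        va <- pick_variant(subject); vb <- pick_variant(object)
        res <- fill_template(tpl, list(A = va$surface, B = vb$surface))
        add_sentence(res, list(c(va, slot = "A"), c(vb, slot = "B")),
                     relation = list(type = rtype, subject = subject,
                                     object = object, planted = planted))
      }
      add_distractor <- function() {
        if (stats::runif(1) < 0.5) {
          tpl <- pick(config$templates$single)
          vx <- pick_variant(pick(names(voc)))
          res <- fill_template(tpl, list(X = vx$surface))
          add_sentence(res, list(c(vx, slot = "X")))
        } else {
          add_sentence(list(text = pick(config$templates$plain),
                            spans = list()), list())
        }
      }
      add_distractor()
      for (k in which(assignment == d)) {
        add_relation_sentence(ev_y$subject_label[k], ev_y$relation_type[k],
                              ev_y$object_label[k], planted = TRUE)
      }
      if (config$noise_rate > 0 && stats::runif(1) < config$noise_rate) {
        pair <- sample(names(voc), 2L)
        add_relation_sentence(pair[1], "RELATED_TO", pair[2], planted = FALSE)
      }
      extra <- config$distractor_sentences_per_doc - 1L
      if (extra > 0L) for (k in seq_len(extra)) add_distractor()
      docs[[length(docs) + 1L]] <- data.frame(
        doc_id = doc_id, year = y, title = NA_character_,
        section = "ABSTRACT", text = paste(sentences, collapse = " "),
        stringsAsFactors = FALSE
      )
    }
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else NULL
  corp <- corpus(if (length(docs)) do.call(rbind, docs) else
                 data.frame(doc_id = character(), year = integer(),
                            text = character()))
  structure(list(
    corpus = corp,
    gold_mentions = bind(gold_m),
    gold_relations = bind(gold_r),
    expected_table = expected_distances(schedule, schedule$flesh_labels,
                                        config$years),
    schedule = schedule,
    config = config,
    lexicon = synth_lexicon(),
    synonyms = synth_synonyms(),
    triggers = synth_triggers(),
    norm_config = synth_normalization_config()
  ), class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "<synthetic_bundle> %d document(s), %d planted event(s), %d tracked node(s)\n",
    nrow(x$corpus$documents), nrow(x$schedule$events),
    length(x$expected_table$labels)))
  invisible(x)
}

#' Expected distance table of a planted schedule (independent oracle)
#'
#' Computes, for every year, the shortest-path distance from each non-flesh
#' schedule label to the nearest flesh label on the cumulative planted edge
#' set, by a self-contained breadth-first search. This oracle is independent
#' of the annotation/network code path and serves as the ground truth that
#' the full pipeline must recover.
#'
#' @param schedule a [planted_schedule()] (or its `events` data.frame).
#' @param flesh_labels canonical trait labels.
#' @param years integer vector of years to tabulate.
#' @return A `distance_table`.
#' @export
expected_distances <- function(schedule, flesh_labels, years) {
  events <- if (inherits(schedule, "planted_schedule")) schedule$events
            else schedule
  years <- as.integer(years)
  tracked <- sort(setdiff(unique(c(events$subject_label,
                                   events$object_label)), flesh_labels))
  d <- matrix(NA_real_, nrow = length(tracked), ncol = length(years))
  for (j in seq_along(years)) {
    cum <- events[events$year <= years[j], , drop = FALSE]
    if (!nrow(cum)) next
    nodes <- unique(c(cum$subject_label, cum$object_label))
    adj <- stats::setNames(vector("list", length(nodes)), nodes)
    for (r in seq_len(nrow(cum))) {
      s <- cum$subject_label[r]; o <- cum$object_label[r]
      adj[[s]] <- union(adj[[s]], o)
      adj[[o]] <- union(adj[[o]], s)
    }
    sources <- intersect(flesh_labels, nodes)
    if (!length(sources)) next
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[sources] <- 0
    queue <- sources
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in adj[[u]]) {
        if (dist[w] > dist[u] + 1) {
          dist[w] <- dist[u] + 1
          queue <- c(queue, w)
        }
      }
    }
    hit <- intersect(tracked, nodes)
    vals <- dist[hit]
    vals[!is.finite(vals)] <- NA_real_
    d[match(hit, tracked), j] <- vals
  }
  new_distance_table(tracked, years, d)
}

#' Run the full pipeline over a synthetic bundle
#'
#' Annotates the generated corpus with the bundle's own lexicon and triggers,
#' normalizes, builds the cumulative yearly network series and tabulates
#' distances for the schedule's tracked labels — the quantity that must match
#' the bundle's `expected_table` for noise-free configurations.
#'
#' @param bundle a `synthetic_bundle` from [generate()].
#' @return List with `series` (the `yearly_series`) and `table` (the
#'   recovered `distance_table`).
#' @export
run_pipeline <- function(bundle) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  series <- build_series(
    bundle$corpus, bundle$lexicon, trig = bundle$triggers,
    syn = bundle$synonyms, config = bundle$norm_config,
    years = bundle$config$years
  )
  tbl <- distance_table(series, bundle$expected_table$labels,
                        bundle$schedule$flesh_labels)
  list(series = series, table = tbl)
}

#' Write a synthetic bundle to disk
#'
#' Emits a corpus directory of per-document `.txt` files, a metadata TSV,
#' gold mention/relation TSVs and the expected distance table CSV.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  txt_dir <- file.path(dir, "corpus")
  dir.create(txt_dir, recursive = TRUE, showWarnings = FALSE)
  docs <- bundle$corpus$documents
  for (i in seq_len(nrow(docs))) {
    writeLines(docs$text[i], file.path(txt_dir, paste0(docs$doc_id[i], ".txt")),
               useBytes = TRUE)
  }
  utils::write.table(docs[, c("doc_id", "year", "section")],
                     file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  write_annotations_tsv(bundle$gold_mentions, file.path(dir, "gold_mentions.tsv"))
  write_annotations_tsv(bundle$gold_relations,
                        file.path(dir, "gold_relations.tsv"))
  write_master_table(bundle$expected_table,
                     file.path(dir, "expected_distances.csv"))
  invisible(dir)
}
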