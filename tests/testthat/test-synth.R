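chain_schedule <- function() {
  planted_schedule(data.frame(
    year = c(2001, 2003),
    subject_label = c("ZEAXANTHIN EPOXIDASE", "ZEAXANTHIN"),
    relation_type = "RELATED_TO",
    object_label = c("ZEAXANTHIN", "FLESH COLOR"),
    stringsAsFactors = FALSE
  ), flesh_labels = "FLESH COLOR")
}

test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(years = 2000:2004, seed = 99)
  b1 <- generate(cfg, chain_schedule())
  b2 <- generate(cfg, chain_schedule())
  expect_identical(b1$corpus$documents, b2$corpus$documents)
  expect_identical(b1$gold_mentions, b2$gold_mentions)
  b3 <- generate(generator_config(years = 2000:2004, seed = 100),
                 chain_schedule())
  expect_false(identical(b1$corpus$documents$text, b3$corpus$documents$text))
})

test_that("every planted event is realized in a document of its year", {
  b <- generate(generator_config(years = 2000:2004, seed = 3), chain_schedule())
  ev <- b$schedule$events
  doc_year <- setNames(b$corpus$documents$year, b$corpus$documents$doc_id)
  planted <- b$gold_relations[b$gold_relations$planted, ]
  for (k in seq_len(nrow(ev))) {
    hit <- planted$source_canonical == ev$subject_label[k] &
           planted$target_canonical == ev$object_label[k] &
           doc_year[planted$doc_id] == ev$year[k]
    expect_true(any(hit), info = sprintf("event %d", k))
  }
})

test_that("distractor sentences carry at most one entity", {
  b <- generate(generator_config(years = 2000:2003, seed = 12,
                                 distractor_sentences_per_doc = 4),
                chain_schedule())
  gm <- b$gold_mentions
  key <- paste(gm$doc_id, gm$sentence_index)
  rel_key <- paste(b$gold_relations$doc_id, b$gold_relations$sentence_index)
  per_sentence <- table(key)
  multi <- names(per_sentence)[per_sentence > 1]
  expect_true(all(multi %in% rel_key))
})

test_that("the expected-distance oracle follows planted chains year by year", {
  tbl <- expected_distances(chain_schedule(), "FLESH COLOR", 2000:2004)
  expect_equal(unname(tbl$d["ZEAXANTHIN EPOXIDASE", ]), c(NA, NA, NA, 2, 2))
  expect_equal(unname(tbl$d["ZEAXANTHIN", ]), c(NA, NA, NA, 1, 1))

  # single direct event: absent before, 1 from the event year on
  one <- planted_schedule(data.frame(
    year = 2002, subject_label = "AN1", relation_type = "RELATED_TO",
    object_label = "FLESH COLOR"), "FLESH COLOR")
  t1 <- expected_distances(one, "FLESH COLOR", 2000:2004)
  expect_equal(unname(t1$d["AN1", ]), c(NA, NA, 1, 1, 1))

  # chain planted over 3 years approaches 3 -> 2 -> 1
  chain3 <- planted_schedule(data.frame(
    year = c(2000, 2001, 2002),
    subject_label = c("BETA-CAROTENE", "ZEAXANTHIN", "LUTEIN"),
    relation_type = "RELATED_TO",
    object_label = c("ZEAXANTHIN", "LUTEIN", "FLESH COLOR")),
    "FLESH COLOR")
  t3 <- expected_distances(chain3, "FLESH COLOR", 2000:2002)
  expect_equal(unname(t3$d["BETA-CAROTENE", ]), c(NA, NA, 3))

  # empty schedule: empty table
  t0 <- expected_distances(data.frame(year = integer(),
                                      subject_label = character(),
                                      relation_type = character(),
                                      object_label = character()),
                           "FLESH COLOR", 2000:2001)
  expect_length(t0$labels, 0L)
})

test_that("the pipeline recovers the planted distance table exactly", {
  b <- generate(generator_config(years = 2000:2005, seed = 21),
                chain_schedule())
  res <- run_pipeline(b)
  expect_equal(res$table$d, b$expected_table$d)
  expect_equal(res$table$labels, b$expected_table$labels)

  # yearly nesting of nodes and edges
  nets <- res$series$networks
  for (j in seq_along(nets)[-1]) {
    expect_true(all(nets[[j - 1]]$nodes$label %in% nets[[j]]$nodes$label))
    prev_e <- paste(nets[[j - 1]]$edges$source, nets[[j - 1]]$edges$target)
    expect_true(all(prev_e %in% paste(nets[[j]]$edges$source,
                                      nets[[j]]$edges$target)))
  }
})

test_that("gold-consistent annotation scores perfect precision and recall", {
  b <- generate(generator_config(years = 2000:2004, seed = 8,
                                 distractor_sentences_per_doc = 3),
                chain_schedule())
  ann <- annotate_corpus(b$corpus, b$lexicon, trig = b$triggers)
  res <- score_entities(b$gold_mentions, ann$mentions, policy = "EXACT")
  expect_equal(res$precision, 100)
  expect_equal(res$recall, 100)
  expect_equal(res$f1, 100)
})

test_that("noise can only bring transitions forward, never delay them", {
  set.seed(31)
  for (rep in 1:5) {
    sched <- random_schedule()
    b <- generate(generator_config(years = 2000:2004, seed = 400 + rep,
                                   noise_rate = 0.5), sched)
    res <- run_pipeline(b)
    planted_tr <- detect_transitions(b$expected_table, ks = 1:2)
    got_tr <- detect_transitions(res$table, ks = 1:2)
    for (col in c("within_1", "within_2", "first_year_observed")) {
      both <- !is.na(planted_tr[[col]])
      # wherever the planted schedule reaches the threshold, the recovered
      # series reaches it no later
      expect_true(all(got_tr[[col]][both] <= planted_tr[[col]][both]))
    }
  }
})

test_that("schedules are validated against the vocabulary and year range", {
  expect_error(planted_schedule(data.frame(
    year = 2000, subject_label = "NOT A LABEL", relation_type = "RELATED_TO",
    object_label = "FLESH COLOR"), "FLESH COLOR"), "vocabulary")
  expect_error(planted_schedule(data.frame(
    year = 2000, subject_label = "LUTEIN", relation_type = "RELATED_TO",
    object_label = "LUTEIN"), "FLESH COLOR"), "self")
  expect_error(generate(generator_config(years = 2000:2001, seed = 1),
                        chain_schedule()), "year range")
  expect_error(generator_config(noise_rate = 2), "noise_rate")
})

test_that("bundles write a loadable corpus directory", {
  b <- generate(generator_config(years = 2000:2004, seed = 5),
                chain_schedule())
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  x <- load_corpus(file.path(dir, "corpus"), file.path(dir, "metadata.tsv"))
  expect_equal(x$documents$doc_id, b$corpus$documents$doc_id)
  expect_equal(x$documents$text, b$corpus$documents$text)
  back <- read_master_table(file.path(dir, "expected_distances.csv"))
  expect_equal(back$d, b$expected_table$d)
})
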