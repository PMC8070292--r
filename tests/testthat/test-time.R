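toy_series <- function() {
  docs <- data.frame(
    doc_id = c("d2001", "d2003"), year = c(2001L, 2003L),
    text = c("ZEP affects zeaxanthin.",
             "Zeaxanthin affects flesh color."),
    stringsAsFactors = FALSE
  )
  build_series(corpus(docs), toy_lexicon(), years = 2001:2003)
}

test_that("cumulative series grow monotonically and freeze between years", {
  series <- toy_series()
  n1 <- series$networks[["2001"]]
  n2 <- series$networks[["2002"]]
  n3 <- series$networks[["2003"]]
  # no 2002 publications: the 2002 network equals the 2001 network
  expect_equal(n2$edges, n1$edges)
  expect_equal(n2$nodes, n1$nodes)
  # 2003 is a supergraph
  expect_true(all(n1$nodes$label %in% n3$nodes$label))
  expect_true(nrow(n3$edges) > nrow(n1$edges))

  # empty corpus: every yearly network empty
  empty <- build_series(corpus(data.frame(doc_id = character(),
                                          year = integer(),
                                          text = character())),
                        toy_lexicon(), years = 2000:2002)
  expect_true(all(vapply(empty$networks, function(n) nrow(n$nodes) == 0L,
                         logical(1))))
})

test_that("eventual direct neighbors come from the final network", {
  series <- toy_series()
  expect_equal(eventual_direct_neighbors(series, "FLESH COLOR"), "ZEAXANTHIN")
  expect_error(eventual_direct_neighbors(series, "NOT A NODE"), "flesh")
})

test_that("distance cells are minima over flesh nodes with ABSENT for no path", {
  series <- toy_series()
  tbl <- distance_table(series, c("ZEAXANTHIN EPOXIDASE", "ZEAXANTHIN"),
                        "FLESH COLOR")
  # chain gene - metabolite - trait: distance 2 once the trait appears
  expect_equal(unname(tbl$d["ZEAXANTHIN EPOXIDASE", ]), c(NA, NA, 2))
  expect_equal(unname(tbl$d["ZEAXANTHIN", ]), c(NA, NA, 1))

  # minimum over two flesh nodes at distances 3 and 1
  sched <- planted_schedule(data.frame(
    year = c(2000, 2000, 2000, 2000),
    subject_label = c("ZEAXANTHIN EPOXIDASE", "ZEAXANTHIN", "BETA-CAROTENE",
                      "ZEAXANTHIN EPOXIDASE"),
    relation_type = "RELATED_TO",
    object_label = c("ZEAXANTHIN", "BETA-CAROTENE", "FLESH COLOR",
                     "TUBER COLOR")),
    flesh_labels = c("FLESH COLOR", "TUBER COLOR"))
  exp_tbl <- expected_distances(sched, sched$flesh_labels, 2000)
  expect_equal(unname(exp_tbl$d["ZEAXANTHIN EPOXIDASE", 1]), 1)

  # tracked labels overlapping flesh labels are dropped with a warning
  expect_warning(
    distance_table(series, c("ZEAXANTHIN", "FLESH COLOR"), "FLESH COLOR"),
    "dropped")
})

test_that("transition detection reads first crossing years off each row", {
  d <- matrix(c(NA, 3, 2, 2, 1, 1,
                NA, NA, NA, NA, NA, NA,
                1, 1, 1, 1, 1, 1), nrow = 3, byrow = TRUE)
  tbl <- litkn:::new_distance_table(c("g1", "g2", "g3"), 2000:2005, d)
  tr <- detect_transitions(tbl, ks = c(1, 2, 3))
  expect_equal(tr$first_year_observed, c(2001L, NA, 2000L))
  expect_equal(tr$within_3, c(2001L, NA, 2000L))
  expect_equal(tr$within_2, c(2002L, NA, 2000L))
  expect_equal(tr$direct_year, c(2004L, NA, 2000L))
  expect_equal(tr$within_1, tr$direct_year)
  expect_true(all(is.na(tr$first_year_observed) |
                  tr$first_year_observed <= tr$within_1 | is.na(tr$within_1)))

  expect_equal(lead_time(tr, "g1", anchor_year = 2006), 2L)
  expect_equal(lead_time(tr, "g1", anchor_year = 2006, k = 2), 4L)
})

test_that("year_diff lists exactly the changed tracked/flesh distance pairs", {
  docs <- data.frame(
    doc_id = c("a", "b"), year = c(2001L, 2002L),
    text = c("ZEP affects zeaxanthin.", "ZEP affects flesh color."),
    stringsAsFactors = FALSE
  )
  series <- build_series(corpus(docs), toy_lexicon(), years = 2001:2002)
  d <- year_diff(series, c("ZEAXANTHIN EPOXIDASE", "ZEAXANTHIN"),
                 "FLESH COLOR", 2002)
  # ZEP: absent -> 1; zeaxanthin: absent -> 2
  expect_equal(nrow(d), 2L)
  zep <- d[d$tracked_label == "ZEAXANTHIN EPOXIDASE", ]
  expect_true(is.na(zep$old))
  expect_equal(zep$new, 1)

  # unchanged year pair produces an empty diff
  docs2 <- rbind(docs, data.frame(doc_id = "c", year = 2003L,
                                  text = "Nothing new here."))
  series2 <- build_series(corpus(docs2), toy_lexicon(), years = 2001:2003)
  expect_equal(nrow(year_diff(series2, "ZEAXANTHIN", "FLESH COLOR", 2003)), 0L)

  expect_error(year_diff(series, "ZEAXANTHIN", "FLESH COLOR", 2001), "years")
})

test_that("master tables round-trip through CSV exactly", {
  tbl <- table2_master()
  path <- withr::local_tempfile(fileext = ".csv")
  write_master_table(tbl, path)
  back <- read_master_table(path)
  expect_equal(back$labels, tbl$labels)
  expect_equal(back$years, tbl$years)
  expect_equal(back$d, tbl$d)
  # byte-exact rewrite
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_master_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("master table parsing validates cells and warns on monotonicity", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("node,2000,2001", "g,-3,1"), path)
  expect_error(read_master_table(path), "row 1")
  writeLines(c("node,2000,2001", "g,0,1"), path)
  expect_error(read_master_table(path), "row 1")
  writeLines(c("node,2000,2001,2002", "g,1,2,2"), path)
  expect_warning(read_master_table(path), "non-monotone")
  writeLines(c("node,2000,2001,2002", "g,2,x,1"), path)
  expect_warning(read_master_table(path), "non-monotone")
  writeLines(c("node,2000,2001,2002", "g,x,2,1"), path)
  expect_silent(read_master_table(path))
})
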