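triple_row <- function(a, b, doc, ta = "GENE_PROTEIN", tb = "METABOLITE",
                       rel = "RELATED_TO") {
  data.frame(
    relationship_id = paste0(doc, a, b), relation_type = rel,
    subject_mention = a, subject_label = a, subject_type = ta,
    object_mention = b, object_label = b, object_type = tb,
    doc_id = doc, sentence_position = 0L, source_pos = "0:1",
    target_pos = "2:3", stringsAsFactors = FALSE
  )
}

test_that("edge weights count distinct documents and set the color class", {
  tr <- rbind(triple_row("A", "B", "D1"), triple_row("A", "B", "D2"))
  net <- build_network(tr)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 2L)
  expect_equal(net$edges$color_class, "BLACK")
  expect_equal(net$edges$doc_ids, "D1;D2")

  single <- build_network(triple_row("A", "B", "D1"))
  expect_equal(single$edges$weight, 1L)
  expect_equal(single$edges$color_class, "GREY")

  # repeated mentions in one document still weigh 1 under document weighting
  rep1 <- build_network(rbind(triple_row("A", "B", "D1"),
                              triple_row("A", "B", "D1")))
  expect_equal(rep1$edges$weight, 1L)
  expect_equal(build_network(rbind(triple_row("A", "B", "D1"),
                                   triple_row("A", "B", "D1")),
                             weight_by = "mentions")$edges$weight, 2L)
})

test_that("networks have no isolated nodes and collapse pairs across types", {
  tr <- rbind(triple_row("A", "B", "D1"),
              triple_row("B", "C", "D1", ta = "METABOLITE", tb = "TRAIT"))
  net <- build_network(tr)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$nodes$label, c("A", "B", "C"))

  # multiple relation types between one pair collapse onto one edge
  two_types <- build_network(rbind(
    triple_row("A", "B", "D1"),
    triple_row("A", "B", "D2", rel = "ENCODES")))
  expect_equal(nrow(two_types$edges), 1L)
  expect_equal(two_types$edges$relation_types, "ENCODES;RELATED_TO")

  # a label with two entity types is a hard error naming the conflict
  bad <- rbind(triple_row("A", "B", "D1"),
               triple_row("A", "C", "D1", ta = "TRAIT"))
  expect_error(build_network(bad), "conflicting entity types")
})

test_that("build_network is invariant to triple order", {
  set.seed(7)
  tr <- random_triples(n_labels = 8, n_triples = 25)
  net1 <- build_network(tr)
  for (rep in 1:5) {
    net2 <- build_network(tr[sample(nrow(tr)), , drop = FALSE])
    expect_equal(net2$edges, net1$edges)
    expect_equal(net2$nodes, net1$nodes)
  }
})

test_that("network invariants hold on random triple sets", {
  set.seed(11)
  for (rep in 1:20) {
    tr <- random_triples(n_labels = sample(4:12, 1),
                         n_triples = sample(5:30, 1))
    net <- build_network(tr)
    # no self loops, no isolated nodes
    expect_true(all(net$edges$source != net$edges$target))
    expect_setequal(net$nodes$label,
                    unique(c(net$edges$source, net$edges$target)))
    # weight equals |doc_ids| and GREY <=> weight 1
    n_docs <- lengths(strsplit(net$edges$doc_ids, ";", fixed = TRUE))
    expect_equal(net$edges$weight, n_docs)
    expect_equal(net$edges$color_class == "GREY", net$edges$weight == 1L)
  }
})

test_that("network summary counts are consistent", {
  tr <- rbind(triple_row("A", "B", "D1"),
              triple_row("B", "C", "D1", ta = "METABOLITE", tb = "TRAIT"))
  s <- network_summary(build_network(tr))
  expect_equal(s$n_nodes, 3L)
  expect_equal(s$n_edges, 2L)
  expect_equal(unname(s$nodes_by_type),
               c(1L, 1L, 1L))
  expect_equal(s$n_nodes, sum(s$nodes_by_type))

  empty <- network_summary(build_network(NULL))
  expect_equal(empty$n_nodes, 0L)
  expect_equal(empty$n_edges, 0L)
})

test_that("first-order neighbors exclude the focus set and require presence", {
  star <- do.call(rbind, lapply(c("a", "b", "c"), function(l)
    triple_row("X", l, "D1")))
  net <- build_network(star)
  expect_setequal(first_order_neighbors(net, "X")$label, c("a", "b", "c"))
  expect_setequal(first_order_neighbors(net, c("X", "a"))$label, c("b", "c"))
  expect_error(first_order_neighbors(net, "missing"), "focus")
})

test_that("the centroid is the max-degree node with lexicographic tie-break", {
  star <- do.call(rbind, lapply(sprintf("leaf%d", 1:5), function(l)
    triple_row("HUB", l, "D1")))
  expect_equal(centroid(build_network(star))$label, "HUB")
  expect_equal(centroid(build_network(star))$neighbor_count, 5L)

  # two hubs tied at 3 neighbors: smallest label wins
  tied <- rbind(
    do.call(rbind, lapply(c("p", "q", "r"), function(l) triple_row("BBB", l, "D1"))),
    do.call(rbind, lapply(c("u", "v", "w"), function(l) triple_row("AAA", l, "D1"))))
  expect_equal(centroid(build_network(tied))$label, "AAA")

  one <- build_network(triple_row("A", "B", "D1"))
  expect_equal(centroid(one)$label, "A")
  expect_error(centroid(build_network(NULL)), "empty")
})

test_that("set comparison returns A, B and their difference", {
  net_a <- build_network(do.call(rbind, lapply(c("p", "q"), function(l)
    triple_row("T", l, "D1"))))
  net_b <- build_network(triple_row("T", "r", "D1"))
  cmp <- compare_first_order(net_a, net_b, "T")
  expect_equal(cmp$set_a, c("p", "q"))
  expect_equal(cmp$set_b, "r")
  expect_equal(cmp$difference, c("p", "q"))
  expect_length(intersect(cmp$difference, cmp$set_b), 0L)
  expect_true(all(cmp$difference %in% cmp$set_a))

  same <- compare_first_order(net_a, net_a, "T")
  expect_length(same$difference, 0L)

  # focus absent from B: set B is empty
  cmp2 <- compare_first_order(net_a, build_network(triple_row("Z", "y", "D1")),
                              "T")
  expect_length(cmp2$set_b, 0L)
})

test_that("distances agree with the brute-force BFS oracle on random graphs", {
  set.seed(23)
  for (rep in 1:15) {
    tr <- random_triples(n_labels = sample(10:50, 1),
                         n_triples = sample(10:60, 1))
    net <- build_network(tr)
    labels <- net$nodes$label
    targets <- sample(labels, min(3, length(labels)))
    got <- litkn:::dist_to_set(net, labels, targets)
    for (l in labels) {
      want <- oracle_dist_to_set(net$edges, l, targets)
      if (is.infinite(want)) {
        expect_true(is.na(got[[l]]))
      } else {
        expect_equal(got[[l]], want)
      }
    }
  }
})

test_that("cytoscape export is deterministic and carries the edge classes", {
  tr <- rbind(triple_row("A", "B", "D1"), triple_row("A", "B", "D2"),
              triple_row("B", "C", "D1", ta = "METABOLITE", tb = "TRAIT"))
  net <- build_network(tr)
  e1 <- withr::local_tempfile(fileext = ".csv")
  n1 <- withr::local_tempfile(fileext = ".csv")
  export_cytoscape(net, e1, n1)
  edges <- read.csv(e1)
  expect_equal(names(edges), c("source", "target", "relation_types", "weight",
                               "color_class", "doc_ids"))
  expect_equal(nrow(edges), 2L)
  expect_equal(edges$color_class[edges$source == "A"], "BLACK")
  nodes <- read.csv(n1)
  expect_equal(nrow(nodes), 3L)

  e2 <- withr::local_tempfile(fileext = ".csv")
  n2 <- withr::local_tempfile(fileext = ".csv")
  export_cytoscape(net, e2, n2)
  expect_identical(readLines(e1), readLines(e2))
  expect_identical(readLines(n1), readLines(n2))
})
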