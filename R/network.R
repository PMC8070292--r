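#' Build a knowledge network from knowledge triples
#'
#' Nodes are the distinct normalized `(label, entity_type)` pairs that take
#' part in at least one relation (entities without relationships never enter
#' the network, so there are no isolated nodes). Edges are unordered label
#' pairs; each edge records the set of distinct documents it appears in, and
#' its weight is that document frequency. Edges seen in a single document are
#' classed `GREY`, edges seen in more than one `BLACK` — the grey/black
#' distinction separates potentially novel from repeatedly reported
#' associations. Multiple relation types between the same pair collapse onto
#' one edge carrying the set of types.
#'
#' @param triples data.frame with the [triple_columns()] layout (labels
#'   already normalized).
#' @param weight_by `"documents"` (default) weights each edge by the number
#'   of distinct documents it occurs in; `"mentions"` by the number of
#'   relation mentions. The grey/black class always reflects document
#'   frequency.
#' @return Object of class `knowledge_network`: list with `nodes`
#'   (data.frame `label`, `entity_type`), `edges` (data.frame `source`,
#'   `target`, `weight`, `n_docs`, `doc_ids`, `relation_types`,
#'   `color_class`) and `graph` (the underlying [igraph][igraph::igraph]
#'   object).
#' @export
build_network <- function(triples, weight_by = c("documents", "mentions")) {
  weight_by <- match.arg(weight_by)
  nodes_proto <- data.frame(label = character(), entity_type = character(),
                            stringsAsFactors = FALSE)
  edges_proto <- data.frame(
    source = character(), target = character(), weight = integer(),
    n_docs = integer(), doc_ids = character(), relation_types = character(),
    color_class = character(), stringsAsFactors = FALSE
  )
  if (is.null(triples) || nrow(triples) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(nodes = nodes_proto, edges = edges_proto, graph = g),
                     class = "knowledge_network"))
  }
  long <- data.frame(
    label = c(triples$subject_label, triples$object_label),
    entity_type = c(triples$subject_type, triples$object_type),
    stringsAsFactors = FALSE
  )
  types_per_label <- tapply(long$entity_type, long$label,
                            function(t) sort(unique(t)))
  conflict <- names(types_per_label)[lengths(types_per_label) > 1L]
  if (length(conflict)) {
    detail <- vapply(conflict, function(l) {
      sprintf("'%s' (%s)", l, paste(types_per_label[[l]], collapse = " vs "))
    }, character(1))
    stop("entity label(s) carry conflicting entity types: ",
         paste(detail, collapse = "; "), call. = FALSE)
  }
  if (any(triples$subject_label == triples$object_label)) {
    stop("self-loop triple (subject_label == object_label)", call. = FALSE)
  }
  a <- pmin(triples$subject_label, triples$object_label)
  b <- pmax(triples$subject_label, triples$object_label)
  key <- paste(a, b, sep = "\r")
  agg <- lapply(split(seq_len(nrow(triples)), key), function(ix) {
    docs <- sort(unique(triples$doc_id[ix]))
    list(
      source = a[ix[1]], target = b[ix[1]],
      n_docs = length(docs),
      n_mentions = length(ix),
      doc_ids = paste(docs, collapse = ";"),
      relation_types = paste(sort(unique(triples$relation_type[ix])),
                             collapse = ";")
    )
  })
  edges <- data.frame(
    source = vapply(agg, `[[`, character(1), "source"),
    target = vapply(agg, `[[`, character(1), "target"),
    n_docs = vapply(agg, `[[`, integer(1), "n_docs"),
    n_mentions = vapply(agg, `[[`, integer(1), "n_mentions"),
    doc_ids = vapply(agg, `[[`, character(1), "doc_ids"),
    relation_types = vapply(agg, `[[`, character(1), "relation_types"),
    stringsAsFactors = FALSE
  )
  edges$weight <- if (weight_by == "documents") edges$n_docs else edges$n_mentions
  edges$color_class <- ifelse(edges$n_docs == 1L, "GREY", "BLACK")
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  edges <- edges[, c("source", "target", "weight", "n_docs", "doc_ids",
                     "relation_types", "color_class")]
  rownames(edges) <- NULL

  nodes <- unique(long)
  nodes <- nodes[order(nodes$label), , drop = FALSE]
  rownames(nodes) <- NULL

  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "knowledge_network")
}

#' @export
print.knowledge_network <- function(x, ...) {
  cat(sprintf("<knowledge_network> %d node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Summarize a knowledge network
#'
#' Counts nodes (overall and per entity type) and unique edges. The total
#' node count always equals the sum of the per-type counts.
#'
#' @param x a `knowledge_network`, or a named integer vector of per-type node
#'   counts (names from [entity_types()]) when only the node tally is of
#'   interest.
#' @param n_edges edge count to record when `x` is a vector of counts.
#' @return Object of class `network_summary`: list with `n_nodes`, `n_edges`,
#'   `nodes_by_type`.
#' @export
network_summary <- function(x, n_edges = NA_integer_) {
  if (inherits(x, "knowledge_network")) {
    by_type <- stats::setNames(integer(length(entity_types())), entity_types())
    tab <- table(x$nodes$entity_type)
    by_type[names(tab)] <- as.integer(tab)
    out <- list(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                nodes_by_type = by_type)
  } else {
    counts <- x
    bad <- setdiff(names(counts), entity_types())
    if (length(bad)) {
      stop("unknown entity type(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    by_type <- stats::setNames(integer(length(entity_types())), entity_types())
    by_type[names(counts)] <- as.integer(counts)
    out <- list(n_nodes = sum(by_type), n_edges = as.integer(n_edges),
                nodes_by_type = by_type)
  }
  stopifnot(out$n_nodes == sum(out$nodes_by_type))
  structure(out, class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("<network_summary> %d node(s) (%s), %s edge(s)\n", x$n_nodes,
              paste(sprintf("%s: %d", names(x$nodes_by_type), x$nodes_by_type),
                    collapse = ", "),
              ifelse(is.na(x$n_edges), "?", x$n_edges)))
  invisible(x)
}

#' First-order neighbors of a set of focus nodes
#'
#' The union of the direct neighbors of all focus labels, with the focus
#' labels themselves excluded.
#'
#' @param net a `knowledge_network`.
#' @param focus_labels character vector; at least one must be present in the
#'   network.
#' @return data.frame with columns `label`, `entity_type`, sorted by label.
#' @export
first_order_neighbors <- function(net, focus_labels) {
  stopifnot(inherits(net, "knowledge_network"))
  present <- intersect(focus_labels, net$nodes$label)
  if (!length(present)) {
    stop("none of the focus labels are present in the network", call. = FALSE)
  }
  hit <- net$edges$source %in% present | net$edges$target %in% present
  nb <- setdiff(unique(c(net$edges$source[hit], net$edges$target[hit])),
                focus_labels)
  out <- net$nodes[net$nodes$label %in% nb, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Primary centroid of a knowledge network
#'
#' The node with the largest number of distinct first-order neighbors; ties
#' are broken by lexicographically smallest label.
#'
#' @param net a non-empty `knowledge_network`.
#' @return List with `label` and `neighbor_count`.
#' @export
centroid <- function(net) {
  stopifnot(inherits(net, "knowledge_network"))
  if (nrow(net$nodes) == 0L) stop("network is empty", call. = FALSE)
  deg <- igraph::degree(net$graph)  # edges are simple, so degree == #neighbors
  labs <- names(deg)
  best <- order(-deg, labs)[1]
  list(label = labs[best], neighbor_count = as.integer(deg[best]))
}

#' Compare first-order neighbor sets across two networks
#'
#' Computes the first-order neighbors of the focus labels in each network and
#' their difference (set A minus set B, by label) — e.g. entities adjacent to
#' the trait in full-text networks but not in abstract-only networks.
#'
#' @param net_a,net_b `knowledge_network` objects.
#' @param focus_labels focus node labels; must be present in `net_a`. If
#'   absent from `net_b`, set B is empty.
#' @return Object of class `set_comparison`: list of character vectors
#'   `set_a`, `set_b`, `difference` (all sorted).
#' @export
compare_first_order <- function(net_a, net_b, focus_labels) {
  set_a <- sort(first_order_neighbors(net_a, focus_labels)$label)
  set_b <- if (any(focus_labels %in% net_b$nodes$label)) {
    sort(first_order_neighbors(net_b, focus_labels)$label)
  } else character()
  structure(list(set_a = set_a, set_b = set_b,
                 difference = setdiff(set_a, set_b)),
            class = "set_comparison")
}

#' @export
print.set_comparison <- function(x, ...) {
  cat(sprintf("<set_comparison> |A| = %d, |B| = %d, |A - B| = %d\n",
              length(x$set_a), length(x$set_b), length(x$difference)))
  invisible(x)
}

#' Export a knowledge network as Cytoscape-compatible CSV files
#'
#' Writes an edge table (`source,target,relation_types,weight,color_class,
#' doc_ids`) and a node table (`label,entity_type`), both row-sorted so that
#' repeated exports are byte-identical.
#'
#' @param net a `knowledge_network`.
#' @param edge_path,node_path output CSV paths.
#' @export
export_cytoscape <- function(net, edge_path, node_path) {
  stopifnot(inherits(net, "knowledge_network"))
  ed <- net$edges[order(net$edges$source, net$edges$target),
                  c("source", "target", "relation_types", "weight",
                    "color_class", "doc_ids"), drop = FALSE]
  no <- net$nodes[order(net$nodes$label), , drop = FALSE]
  utils::write.csv(ed, edge_path, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(no, node_path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(edge_path, node_path))
}

#' Export a knowledge network in SIF format
#'
#' One line per edge: `source<TAB>relation<TAB>target` (the joined relation
#' type set serves as the interaction label).
#'
#' @param net a `knowledge_network`.
#' @param path output path.
#' @export
export_sif <- function(net, path) {
  stopifnot(inherits(net, "knowledge_network"))
  ed <- net$edges[order(net$edges$source, net$edges$target), , drop = FALSE]
  writeLines(sprintf("%s\t%s\t%s", ed$source, ed$relation_types, ed$target),
             path)
  invisible(path)
}

# Minimum unweighted shortest-path distance from each of `from` to any label
# in `to_set`, within one network. Returns NA for absent/unreachable nodes.
dist_to_set <- function(net, from, to_set) {
  res <- stats::setNames(rep(NA_real_, length(from)), from)
  if (nrow(net$nodes) == 0L) return(res)
  from_in <- intersect(from, net$nodes$label)
  to_in <- intersect(to_set, net$nodes$label)
  if (!length(from_in) || !length(to_in)) return(res)
  d <- igraph::distances(net$graph, v = from_in, to = to_in, weights = NA)
  m <- apply(d, 1, min)
  m[!is.finite(m)] <- NA_real_
  res[from_in] <- m
  res
}
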