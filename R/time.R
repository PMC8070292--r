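#' Build a cumulative yearly series of knowledge networks
#'
#' For every year in `years` the network is built from all documents
#' published up to and including that year, so each yearly network is a
#' subgraph of every later one and a supergraph of every earlier one.
#' Annotation runs once over the full corpus (it is a per-document
#' operation); each yearly network is then assembled from the triples of the
#' documents in that cumulative slice.
#'
#' @param x a [corpus].
#' @param lex a [lexicon].
#' @param trig optional trigger table; see [extract_relations()].
#' @param syn optional [synonym_table()].
#' @param config a [normalization_config()].
#' @param years ascending integer vector of years; default
#'   `min(year):max(year)` over the corpus.
#' @param known extra known labels for normalization; defaults to the lexicon
#'   preferred labels.
#' @param abbreviations passed to [segment_sentences()].
#' @return Object of class `yearly_series`: list with `years` and `networks`
#'   (one `knowledge_network` per year, named by year).
#' @export
build_series <- function(x, lex, trig = NULL, syn = NULL,
                         config = normalization_config(), years = NULL,
                         known = NULL,
                         abbreviations = default_abbreviations()) {
  stopifnot(inherits(x, "corpus"))
  if (is.null(years)) {
    if (nrow(x$documents) == 0L) {
      stop("cannot infer years from an empty corpus; supply `years`",
           call. = FALSE)
    }
    years <- seq(min(x$documents$year), max(x$documents$year))
  }
  years <- as.integer(years)
  if (is.unsorted(years, strictly = TRUE)) {
    stop("`years` must be strictly ascending", call. = FALSE)
  }
  if (is.null(known)) known <- unique(lex$preferred_label)
  ann <- annotate_corpus(x, lex, trig = trig, abbreviations = abbreviations)
  triples <- to_triples(ann$relations, syn = syn, config = config, known = known)
  doc_year <- stats::setNames(x$documents$year, x$documents$doc_id)
  networks <- lapply(years, function(y) {
    build_network(triples[doc_year[triples$doc_id] <= y, , drop = FALSE])
  })
  names(networks) <- as.character(years)
  structure(list(years = years, networks = networks), class = "yearly_series")
}

#' @export
print.yearly_series <- function(x, ...) {
  cat(sprintf("<yearly_series> %d year(s): %d-%d\n", length(x$years),
              min(x$years), max(x$years)))
  invisible(x)
}

#' Eventual direct neighbors of the trait node set
#'
#' The labels directly connected to any of the designated trait ("flesh")
#' nodes in the final year's network — the candidate set whose approach to
#' the trait is tracked backwards through time.
#'
#' @param series a `yearly_series`.
#' @param flesh_labels non-empty character vector of trait node labels.
#' @return Sorted character vector of labels (flesh labels excluded).
#' @export
eventual_direct_neighbors <- function(series, flesh_labels) {
  stopifnot(inherits(series, "yearly_series"), length(flesh_labels) >= 1L)
  final <- series$networks[[length(series$networks)]]
  if (!any(flesh_labels %in% final$nodes$label)) {
    stop("no flesh label present in the final year's network", call. = FALSE)
  }
  sort(first_order_neighbors(final, flesh_labels)$label)
}

new_distance_table <- function(labels, years, d) {
  stopifnot(is.matrix(d), nrow(d) == length(labels), ncol(d) == length(years))
  dimnames(d) <- list(labels, as.character(years))
  structure(list(labels = as.character(labels), years = as.integer(years),
                 d = d), class = "distance_table")
}

#' @export
print.distance_table <- function(x, ...) {
  cat(sprintf("<distance_table> %d tracked node(s) x %d year(s)\n",
              length(x$labels), length(x$years)))
  if (length(x$labels)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' @export
as.data.frame.distance_table <- function(x, ...) {
  cells <- ifelse(is.na(x$d), "x", as.character(x$d))
  out <- data.frame(node = x$labels, cells, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out) <- c("node", as.character(x$years))
  out
}

#' Master distance table of tracked nodes versus years
#'
#' For every tracked label and every year, the unweighted shortest-path
#' distance from that node to the nearest flesh node in that year's network.
#' A cell is absent (`NA`, rendered `"x"`) when the tracked node is not yet
#' in the network or no path to any flesh node exists. Because the yearly
#' corpora are cumulative, each row is non-increasing once numeric.
#'
#' @param series a `yearly_series`.
#' @param tracked character vector of tracked labels; must all be nodes of
#'   the final year's network. Labels that are themselves flesh labels are
#'   dropped with a warning.
#' @param flesh_labels character vector of trait node labels.
#' @return Object of class `distance_table`.
#' @export
distance_table <- function(series, tracked, flesh_labels) {
  stopifnot(inherits(series, "yearly_series"))
  overlap <- intersect(tracked, flesh_labels)
  if (length(overlap)) {
    warning("tracked label(s) are flesh labels and were dropped: ",
            paste(overlap, collapse = ", "), call. = FALSE)
    tracked <- setdiff(tracked, flesh_labels)
  }
  final <- series$networks[[length(series$networks)]]
  absent <- setdiff(tracked, final$nodes$label)
  if (length(absent)) {
    stop("tracked label(s) missing from the final network: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  d <- matrix(NA_real_, nrow = length(tracked), ncol = length(series$years))
  for (j in seq_along(series$years)) {
    d[, j] <- dist_to_set(series$networks[[j]], tracked, flesh_labels)
  }
  new_distance_table(tracked, series$years, d)
}

#' Detect proximity transitions of tracked nodes
#'
#' For each tracked label, reports the first year it appears at any finite
#' distance, the first year its distance is at most `k` for each requested
#' threshold, and the first year it becomes a direct neighbor (distance 1).
#'
#' @param tbl a `distance_table`.
#' @param ks positive integer thresholds; 1 is always included.
#' @return data.frame with columns `label`, `first_year_observed`,
#'   `direct_year` and one `within_<k>` column per threshold (`NA` where the
#'   condition is never met).
#' @export
detect_transitions <- function(tbl, ks = c(1L, 2L)) {
  stopifnot(inherits(tbl, "distance_table"))
  ks <- sort(unique(c(1L, as.integer(ks))))
  if (any(ks < 1L)) stop("thresholds must be positive", call. = FALSE)
  first_year_where <- function(v, cond) {
    i <- which(cond(v))
    if (length(i)) tbl$years[min(i)] else NA_integer_
  }
  out <- data.frame(
    label = tbl$labels,
    first_year_observed = vapply(seq_along(tbl$labels), function(r) {
      first_year_where(tbl$d[r, ], function(v) !is.na(v))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  for (k in ks) {
    out[[sprintf("within_%d", k)]] <-
      vapply(seq_along(tbl$labels), function(r) {
        first_year_where(tbl$d[r, ], function(v) !is.na(v) & v <= k)
      }, integer(1))
  }
  out$direct_year <- out$within_1
  rownames(out) <- NULL
  out
}

#' Lead time between a detected transition and an anchor year
#'
#' Convenience helper: how many years before a caller-supplied anchor (for
#' example the year explicit experimental evidence was published) a tracked
#' node first came within distance `k` of the trait set. The anchor is not
#' inferred from the data.
#'
#' @param transitions data.frame from [detect_transitions()].
#' @param label tracked label.
#' @param anchor_year integer anchor year.
#' @param k threshold whose `within_<k>` column is used (default 1).
#' @return Integer lead time in years (`NA` if the transition never occurs).
#' @export
lead_time <- function(transitions, label, anchor_year, k = 1L) {
  row <- match(label, transitions$label)
  if (is.na(row)) stop("unknown label: ", label, call. = FALSE)
  col <- sprintf("within_%d", as.integer(k))
  if (!col %in% names(transitions)) {
    stop("transitions table has no column ", col, call. = FALSE)
  }
  as.integer(anchor_year) - transitions[[col]][row]
}

#' Single-year difference report
#'
#' For consecutive years `to_year - 1` and `to_year`, lists every
#' (tracked label, individual flesh node) pair whose shortest-path distance
#' changed, with the old and new values.
#'
#' @param series a `yearly_series`.
#' @param tracked tracked labels (see [distance_table()]).
#' @param flesh_labels individual flesh node labels.
#' @param to_year the later of the two years; both years must be in the
#'   series.
#' @return data.frame with columns `from_year`, `to_year`, `tracked_label`,
#'   `flesh_label`, `old`, `new` (`NA` for absent).
#' @export
year_diff <- function(series, tracked, flesh_labels, to_year) {
  stopifnot(inherits(series, "yearly_series"))
  to_year <- as.integer(to_year)
  from_year <- to_year - 1L
  if (!all(c(from_year, to_year) %in% series$years)) {
    stop(sprintf("both %d and %d must be years of the series", from_year,
                 to_year), call. = FALSE)
  }
  tracked <- setdiff(tracked, flesh_labels)
  net_old <- series$networks[[as.character(from_year)]]
  net_new <- series$networks[[as.character(to_year)]]
  rows <- list()
  for (f in flesh_labels) {
    old <- dist_to_set(net_old, tracked, f)
    new <- dist_to_set(net_new, tracked, f)
    changed <- which(!(is.na(old) & is.na(new)) &
                     (is.na(old) != is.na(new) |
                      (!is.na(old) & !is.na(new) & old != new)))
    if (length(changed)) {
      rows[[length(rows) + 1L]] <- data.frame(
        from_year = from_year, to_year = to_year,
        tracked_label = tracked[changed], flesh_label = f,
        old = old[changed], new = new[changed],
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(from_year = integer(), to_year = integer(),
                      tracked_label = character(), flesh_label = character(),
                      old = numeric(), new = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$tracked_label, out$flesh_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a single-year difference report to CSV
#'
#' Absent distances are written as `"x"`.
#'
#' @param diff data.frame from [year_diff()].
#' @param path output path.
#' @export
write_diff_csv <- function(diff, path) {
  out <- diff
  out$old <- ifelse(is.na(out$old), "x", as.character(out$old))
  out$new <- ifelse(is.na(out$new), "x", as.character(out$new))
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a master distance table to CSV
#'
#' Header `node,<year1>,...,<yearN>`; cells are positive integers or `"x"`
#' for absent.
#'
#' @param tbl a `distance_table`.
#' @param path output path.
#' @export
write_master_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "distance_table"))
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a master distance table from CSV
#'
#' Expects the layout written by [write_master_table()]. Malformed cells are
#' hard errors reported with row and column; per-row monotonicity violations
#' (a distance increasing over time, or a node disappearing after having been
#' observed) are reported as warnings because the file may come from an
#' external source.
#'
#' @param path CSV path.
#' @return A `distance_table`.
#' @export
read_master_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                       fileEncoding = "UTF-8")
  if (names(x)[1] != "node" || ncol(x) < 2L) {
    stop("master table must have header node,<year>,...", call. = FALSE)
  }
  years <- suppressWarnings(as.integer(names(x)[-1]))
  if (anyNA(years)) stop("non-integer year in master table header",
                         call. = FALSE)
  d <- matrix(NA_real_, nrow = nrow(x), ncol = length(years))
  for (j in seq_along(years)) {
    col <- trimws(x[[j + 1L]])
    for (i in seq_along(col)) {
      if (tolower(col[i]) == "x") next
      if (!grepl("^[0-9]+$", col[i]) || as.integer(col[i]) < 1L) {
        stop(sprintf("malformed cell at row %d, year %d: '%s'", i, years[j],
                     col[i]), call. = FALSE)
      }
      d[i, j] <- as.numeric(col[i])
    }
  }
  tbl <- new_distance_table(x$node, years, d)
  viol <- check_row_monotonicity(tbl)
  if (length(viol)) {
    warning("non-monotone row(s) in master table: ",
            paste(viol, collapse = ", "), call. = FALSE)
  }
  tbl
}

# Labels whose rows violate cumulative monotonicity: once numeric a row must
# stay numeric and never increase.
check_row_monotonicity <- function(tbl) {
  bad <- character()
  for (r in seq_along(tbl$labels)) {
    v <- tbl$d[r, ]
    num <- which(!is.na(v))
    if (!length(num)) next
    span <- seq(min(num), length(v))
    if (anyNA(v[span]) || any(diff(v[span]) > 0)) {
      bad <- c(bad, tbl$labels[r])
    }
  }
  bad
}
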