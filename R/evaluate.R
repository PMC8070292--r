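#' F1 score from precision and recall
#'
#' Harmonic mean of precision and recall, on the percentage scale.
#'
#' @param precision,recall percentages in `[0, 100]`.
#' @return F1 percentage (0 when both inputs are 0).
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Load gold entity annotations from TSV
#'
#' Tab-separated with header `doc_id`, `sentence_index`, `start`, `end`,
#' `entity_type` (0-based half-open offsets within the sentence).
#'
#' @param path TSV path.
#' @return data.frame of gold annotations.
#' @export
load_gold_tsv <- function(path) {
  g <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                         fileEncoding = "UTF-8")
  need <- c("doc_id", "sentence_index", "start", "end", "entity_type")
  if (!all(need %in% names(g))) {
    stop("gold TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  g$doc_id <- as.character(g$doc_id)
  g[, need]
}

#' Score predicted entity mentions against gold annotations
#'
#' Pools true positives, false positives and false negatives over all
#' documents (micro-averaging) and computes precision `TP / (TP + FP)`,
#' recall `TP / (TP + FN)` and their harmonic mean F1, all as percentages.
#' Matching is greedy left-to-right with each gold annotation matched at most
#' once. Under the `EXACT` policy a prediction matches a gold annotation with
#' identical document, sentence, span and type; under `OVERLAP` the spans
#' only need to intersect (types must still agree).
#'
#' @param gold data.frame with columns `doc_id`, `sentence_index`, `start`,
#'   `end`, `entity_type`.
#' @param predicted data.frame with the same columns (extra columns such as
#'   those of [find_mentions()] output are ignored).
#' @param policy `"EXACT"` or `"OVERLAP"`.
#' @return Object of class `eval_result`: list with per-document confusion
#'   `rows` (`doc_id`, `total_gold`, `tp`, `fn`, `fp`), pooled counts and
#'   `precision`, `recall`, `f1`.
#' @export
score_entities <- function(gold, predicted, policy = c("EXACT", "OVERLAP")) {
  policy <- match.arg(policy)
  cols <- c("doc_id", "sentence_index", "start", "end", "entity_type")
  for (nm in cols) {
    if (!nm %in% names(gold)) stop("gold lacks column ", nm, call. = FALSE)
    if (!nm %in% names(predicted)) stop("predicted lacks column ", nm,
                                        call. = FALSE)
  }
  gold <- gold[, cols]
  predicted <- predicted[, cols]
  docs <- sort(unique(c(gold$doc_id, predicted$doc_id)))
  z <- integer(length(docs))
  rows <- data.frame(doc_id = docs, total_gold = z, tp = z, fn = z,
                     fp = z, stringsAsFactors = FALSE)
  for (i in seq_along(docs)) {
    g <- gold[gold$doc_id == docs[i], , drop = FALSE]
    p <- predicted[predicted$doc_id == docs[i], , drop = FALSE]
    p <- p[order(p$sentence_index, p$start, p$end), , drop = FALSE]
    g <- g[order(g$sentence_index, g$start, g$end), , drop = FALSE]
    taken <- logical(nrow(g))
    tp <- 0L
    for (k in seq_len(nrow(p))) {
      match_j <- 0L
      for (j in seq_len(nrow(g))) {
        if (taken[j]) next
        if (g$sentence_index[j] != p$sentence_index[k] ||
            g$entity_type[j] != p$entity_type[k]) next
        hit <- if (policy == "EXACT") {
          g$start[j] == p$start[k] && g$end[j] == p$end[k]
        } else {
          p$start[k] < g$end[j] && g$start[j] < p$end[k]
        }
        if (hit) { match_j <- j; break }
      }
      if (match_j > 0L) { taken[match_j] <- TRUE; tp <- tp + 1L }
    }
    rows$total_gold[i] <- nrow(g)
    rows$tp[i] <- tp
    rows$fn[i] <- nrow(g) - tp
    rows$fp[i] <- nrow(p) - tp
  }
  tp <- sum(rows$tp); fp <- sum(rows$fp); fn <- sum(rows$fn)
  precision <- if (tp + fp == 0) { if (fn == 0) 100 else 0 } else 100 * tp / (tp + fp)
  recall <- if (tp + fn == 0) { if (fp == 0) 100 else 0 } else 100 * tp / (tp + fn)
  structure(list(rows = rows, tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall,
                 f1 = f1_score(precision, recall), policy = policy),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> %s matching: P = %.2f%%, R = %.2f%%, F1 = %.2f%% (TP %d, FP %d, FN %d)\n",
    x$policy, x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Write the per-document confusion matrix to CSV
#'
#' Columns `doc_id,total_gold,tp,fn,fp`, one row per document plus a final
#' `TOTAL` aggregate row.
#'
#' @param result an `eval_result` from [score_entities()].
#' @param path output path.
#' @export
write_confusion_csv <- function(result, path) {
  stopifnot(inherits(result, "eval_result"))
  rows <- result$rows
  total <- data.frame(doc_id = "TOTAL", total_gold = sum(rows$total_gold),
                      tp = result$tp, fn = result$fn, fp = result$fp,
                      stringsAsFactors = FALSE)
  utils::write.csv(rbind(rows, total), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
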