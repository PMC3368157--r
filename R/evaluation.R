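# Scoring: single-label sentence protocol, exact/soft trigger-boundary
# matching, per-class precision/recall/F1 reports.

prf_from_counts <- function(tp, fp, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp); fn <- as.numeric(fn)
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

# assemble a per-class report data.frame + macro averages
class_report <- function(tp, fp, fn) {
  rows <- t(vapply(EVENT_TYPES, function(ty)
    prf_from_counts(tp[ty], fp[ty], fn[ty]), numeric(3)))
  report <- data.frame(event_type = EVENT_TYPES, rows,
                       tp = unname(tp[EVENT_TYPES]),
                       fp = unname(fp[EVENT_TYPES]),
                       fn = unname(fn[EVENT_TYPES]),
                       row.names = NULL, stringsAsFactors = FALSE)
  macro <- colMeans(report[, c("precision", "recall", "f1")])
  structure(list(per_class = report, macro = macro), class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  cat(format_class_report(x), sep = "\n")
  invisible(x)
}

#' Format a per-class report as an aligned text table
#'
#' Event types as rows, percentage precision/recall/F1 as columns, with an
#' unweighted (macro) average row.
#'
#' @param report \code{class_report} object.
#' @return Character vector of table lines.
#' @export
format_class_report <- function(report) {
  df <- report$per_class
  fmt <- function(x) sprintf("%6.2f", x)
  lines <- sprintf("%-22s %8s %8s %8s", "Event type", "P", "R", "F1")
  for (i in seq_len(nrow(df)))
    lines <- c(lines, sprintf("%-22s %8s %8s %8s", df$event_type[i],
                              fmt(df$precision[i]), fmt(df$recall[i]),
                              fmt(df$f1[i])))
  lines <- c(lines, sprintf("%-22s %8s %8s %8s", "Average",
                            fmt(report$macro[["precision"]]),
                            fmt(report$macro[["recall"]]),
                            fmt(report$macro[["f1"]])))
  lines
}

#' Evaluate single-label sentence predictions
#'
#' A prediction is correct iff it equals the modal gold event of the
#' sentence; when several events tie for the maximal multiplicity the
#' prediction is correct if it matches any of them.  Per-class counts are
#' derived from the correctness-resolved confusion: a correct prediction is
#' a true positive for the predicted class; a wrong one is a false positive
#' for the predicted class and a false negative for the first modal gold
#' event in declaration order.
#'
#' @param predictions Named character vector, sentence id -> predicted
#'   event type; must cover every gold sentence.
#' @param gold List of gold sentences: \code{list(id = ..., events =
#'   <character vector with multiplicity>)}.
#' @return List with \code{accuracy} (proportion) and \code{report}
#'   (\code{class_report}).
#' @export
eval_single_label <- function(predictions, gold) {
  tp <- fp <- fn <- setNames(numeric(length(EVENT_TYPES)), EVENT_TYPES)
  n_correct <- 0L
  for (g in gold) {
    if (!(g$id %in% names(predictions)))
      stop("missing prediction for sentence id: ", g$id)
    pred <- predictions[[g$id]]
    counts <- table(g$events)
    modal <- names(counts)[counts == max(counts)]
    modal <- modal[order(match(modal, EVENT_TYPES))]
    if (pred %in% modal) {
      n_correct <- n_correct + 1L
      tp[pred] <- tp[pred] + 1
    } else {
      fp[pred] <- fp[pred] + 1
      fn[modal[1]] <- fn[modal[1]] + 1
    }
  }
  list(accuracy = n_correct / length(gold), report = class_report(tp, fp, fn))
}

#' Match a predicted trigger span against a gold span
#'
#' Spans are token-index intervals (0-based half-open) with an event type.
#' \code{exact}: identical interval and identical type.  \code{soft}:
#' identical type, and both boundaries within one token of the gold span.
#'
#' @param pred,gold Lists/rows with \code{start_token}, \code{end_token},
#'   \code{type}.
#' @param mode \code{"exact"} or \code{"soft"}.
#' @return Logical scalar.
#' @export
match_boundary <- function(pred, gold, mode = c("exact", "soft")) {
  mode <- match.arg(mode)
  if (!identical(as.character(pred$type), as.character(gold$type)))
    return(FALSE)
  if (mode == "exact")
    return(pred$start_token == gold$start_token &&
           pred$end_token == gold$end_token)
  abs(pred$start_token - gold$start_token) <= 1L &&
    abs(pred$end_token - gold$end_token) <= 1L
}

# greedy per-sentence matching: gold spans in order, first unmatched
# matching prediction; returns per-sentence logical vectors
match_spans <- function(pred, gold, mode) {
  sentences <- union(unique(gold$sentence_id), unique(pred$sentence_id))
  matches <- list()
  for (sid in sentences) {
    g <- gold[gold$sentence_id == sid, , drop = FALSE]
    p <- pred[pred$sentence_id == sid, , drop = FALSE]
    g <- g[order(g$start_token), , drop = FALSE]
    p <- p[order(p$start_token), , drop = FALSE]
    used <- rep(FALSE, nrow(p))
    gold_hit <- rep(FALSE, nrow(g))
    gold_cls <- g$type
    pair_cls <- character(0)
    for (i in seq_len(nrow(g))) {
      for (j in seq_len(nrow(p))) {
        if (used[j]) next
        if (match_boundary(p[j, ], g[i, ], mode)) {
          used[j] <- TRUE; gold_hit[i] <- TRUE
          pair_cls <- c(pair_cls, g$type[i])
          break
        }
      }
    }
    matches[[as.character(sid)]] <- list(
      gold_hit = gold_hit, pred_used = used,
      gold_type = g$type, pred_type = p$type, matched_type = pair_cls)
  }
  matches
}

#' Trigger-span coverage (percent of gold spans matched)
#'
#' Greedy one-to-one matching per sentence; coverage is
#' \eqn{100 \times} matched gold / total gold.  Soft coverage is always at
#' least the exact coverage.
#'
#' @param pred,gold data.frames with columns sentence_id, start_token,
#'   end_token, type.
#' @param mode \code{"exact"} or \code{"soft"}.
#' @return Percentage in [0, 100].
#' @export
coverage <- function(pred, gold, mode = c("exact", "soft")) {
  mode <- match.arg(mode)
  if (nrow(gold) == 0L) return(100)
  m <- match_spans(pred, gold, mode)
  matched <- sum(vapply(m, function(s) sum(s$gold_hit), numeric(1)))
  100 * matched / nrow(gold)
}

#' Span-level precision/recall/F1 report
#'
#' True positives are matched pairs (greedy per-sentence matching under the
#' given boundary mode), false positives unmatched predictions, false
#' negatives unmatched gold spans; per-class and macro-averaged.
#'
#' @inheritParams coverage
#' @return \code{class_report}.
#' @export
span_prf <- function(pred, gold, mode = c("exact", "soft")) {
  mode <- match.arg(mode)
  tp <- fp <- fn <- setNames(numeric(length(EVENT_TYPES)), EVENT_TYPES)
  m <- match_spans(pred, gold, mode)
  for (s in m) {
    for (ty in s$matched_type) tp[ty] <- tp[ty] + 1
    for (ty in s$pred_type[!s$pred_used]) fp[ty] <- fp[ty] + 1
    for (ty in s$gold_type[!s$gold_hit]) fn[ty] <- fn[ty] + 1
  }
  class_report(tp, fp, fn)
}
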