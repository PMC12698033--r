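#' @title Extraction and study scoring metrics
#' @description Scores concept extraction against gold-standard span
#'   annotations (per-CUI precision/recall/F1), checklist response accuracy,
#'   and the two study instruments: NASA-TLX (six 0-20 subscales weighted to
#'   0-100) and SUS (ten 1-5 Likert items scored to 0-100).
#' @name evaluation_metrics
NULL

#' Gold annotation set
#'
#' Expert span labels, produced independently of the tagger. Stored as one
#' data frame with 0-based half-open spans.
#'
#' @param doc_id,start,end,cui,negated parallel vectors, one entry per gold
#'   mention.
#' @return data frame with class `gold_annotations`.
#' @export
gold_annotations <- function(doc_id = character(0), start = integer(0),
                             end = integer(0), cui = character(0),
                             negated = logical(0)) {
  df <- data.frame(doc_id = as.character(doc_id), start = as.integer(start),
                   end = as.integer(end), cui = as.character(cui),
                   negated = as.logical(negated), stringsAsFactors = FALSE)
  class(df) <- c("gold_annotations", "data.frame")
  df
}

#' @rdname gold_annotations
#' @param path JSONL file, one gold mention per line.
#' @param gold a `gold_annotations` frame.
#' @export
write_gold <- function(gold, path) {
  lines <- vapply(seq_len(nrow(gold)), function(i) {
    as.character(jsonlite::toJSON(
      list(doc_id = gold$doc_id[i], start = gold$start[i], end = gold$end[i],
           cui = gold$cui[i], negated = gold$negated[i], source = "gold"),
      auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname gold_annotations
#' @export
read_gold <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gold_annotations())
  rows <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  gold_annotations(vapply(rows, `[[`, character(1), "doc_id"),
                   vapply(rows, function(x) as.integer(x$start), integer(1)),
                   vapply(rows, function(x) as.integer(x$end), integer(1)),
                   vapply(rows, `[[`, character(1), "cui"),
                   vapply(rows, function(x) isTRUE(x$negated), logical(1)))
}

spans_match <- function(ps, pe, gs, ge, policy) {
  if (policy == "exact") ps == gs & pe == ge
  else ps < ge & gs < pe  # any overlap of half-open spans
}

#' Precision / recall / F1 per concept
#'
#' A predicted affirmed annotation matches a gold affirmed item iff the
#' CUIs agree and the spans overlap (`policy = "overlap"`, the default) or
#' coincide (`policy = "exact"`). Negated predictions do not count as
#' detections, and gold items flagged negated are not expected detections;
#' both are excluded before tallying. Per CUI: TP = gold items with at least
#' one match, FN = the rest, FP = predictions matching no gold item.
#' Zero-denominator precision/recall are reported as `NA` ("n/a"), not 0 or
#' 1; F1 is the harmonic mean (0 when P + R = 0, `NA` when either is `NA`).
#'
#' @param predicted annotation data frame (or [annotate_record()] list).
#' @param gold a [gold_annotations()] frame.
#' @param policy `"overlap"` or `"exact"` span matching.
#' @param doc_ids optional character vector of all known document ids; gold
#'   rows referencing other documents are an error.
#' @return data frame with class `prf_report`: one row per CUI with columns
#'   `cui`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
concept_prf <- function(predicted, gold, policy = c("overlap", "exact"),
                        doc_ids = NULL) {
  policy <- match.arg(policy)
  pred <- combine_annotations(predicted)
  if (!is.null(doc_ids)) {
    bad <- setdiff(unique(gold$doc_id), doc_ids)
    if (length(bad))
      stop("gold annotations reference unknown doc_id(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  pred <- pred[!pred$negated, , drop = FALSE]
  gold <- gold[!gold$negated, , drop = FALSE]
  cuis <- sort(unique(c(pred$cui, gold$cui)))
  rows <- lapply(cuis, function(cui) {
    p <- pred[pred$cui == cui, , drop = FALSE]
    g <- gold[gold$cui == cui, , drop = FALSE]
    g_matched <- logical(nrow(g))
    p_matched <- logical(nrow(p))
    for (i in seq_len(nrow(p))) {
      for (j in seq_len(nrow(g))) {
        if (p$doc_id[i] == g$doc_id[j] &&
            spans_match(p$start[i], p$end[i], g$start[j], g$end[j], policy)) {
          p_matched[i] <- TRUE
          g_matched[j] <- TRUE
        }
      }
    }
    tp <- sum(g_matched)
    fp <- sum(!p_matched)
    fn <- sum(!g_matched)
    precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
    recall <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(precision) || is.na(recall)) NA_real_
    else if (precision + recall == 0) 0
    else 2 * precision * recall / (precision + recall)
    data.frame(cui = cui, tp = tp, fp = fp, fn = fn, precision = precision,
               recall = recall, f1 = f1, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(cui = character(0), tp = integer(0), fp = integer(0),
                  fn = integer(0), precision = numeric(0), recall = numeric(0),
                  f1 = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("prf_report", "data.frame")
  out
}

#' Checklist response accuracy
#'
#' Each correct response earns one point; the accuracy score (maximum 1) is
#' the average over all criteria of the checklist.
#'
#' @param responses character vector of per-criterion answers.
#' @param reference consensus reference answers, same criteria, same order.
#' @return list with `n_items`, `n_correct`, `accuracy`.
#' @export
checklist_accuracy <- function(responses, reference) {
  if (length(responses) != length(reference))
    stop("responses and reference must have the same length", call. = FALSE)
  if (!length(responses))
    stop("cannot score an empty checklist", call. = FALSE)
  n_correct <- sum(responses == reference)
  list(n_items = length(responses), n_correct = n_correct,
       accuracy = n_correct / length(responses))
}

#' NASA-TLX workload score
#'
#' Six subscales (mental, physical and temporal demand, performance, effort,
#' frustration) rated 0-20, higher meaning greater workload. With weights
#' (pairwise-comparison counts summing to 15) the score is
#' `(sum(w * r) / 15) * 5`, mapping the weighted 0-20 mean onto 0-100. With
#' `weights = NULL` the unweighted "raw TLX" mean is used instead and the
#' result is flagged `weighting = "raw"`.
#'
#' @param ratings numeric vector of 6 subscale ratings in \[0, 20\].
#' @param weights 6 non-negative integers summing to 15, or `NULL`.
#' @return list with `score` (0-100) and `weighting` ("weighted" or "raw").
#' @export
nasa_tlx_score <- function(ratings, weights = NULL) {
  if (length(ratings) != 6L || any(!is.finite(ratings)))
    stop("ratings must be 6 finite values", call. = FALSE)
  if (any(ratings < 0 | ratings > 20))
    stop("ratings must lie in [0, 20]", call. = FALSE)
  if (is.null(weights))
    return(list(score = mean(ratings) * 5, weighting = "raw"))
  if (length(weights) != 6L || any(weights < 0) ||
      any(weights != round(weights)) || sum(weights) != 15)
    stop("weights must be 6 non-negative integers summing to 15",
         call. = FALSE)
  list(score = sum(weights * ratings) / 15 * 5, weighting = "weighted")
}

#' System Usability Scale score
#'
#' Standard SUS scoring of the 10-item Likert questionnaire: odd items
#' contribute `response - 1`, even items `5 - response`; the sum is scaled
#' by 2.5 onto 0-100.
#'
#' @param responses exactly 10 integers in 1..5.
#' @return score in \[0, 100\].
#' @export
sus_score <- function(responses) {
  if (length(responses) != 10L)
    stop("SUS requires exactly 10 responses", call. = FALSE)
  if (any(!is.finite(responses)) || any(responses < 1 | responses > 5))
    stop("SUS responses must lie in 1..5", call. = FALSE)
  odd <- responses[c(1, 3, 5, 7, 9)] - 1
  even <- 5 - responses[c(2, 4, 6, 8, 10)]
  (sum(odd) + sum(even)) * 2.5
}

#' Write a per-concept metric report as CSV
#' @param report a `prf_report`.
#' @param path CSV path.
#' @export
write_prf_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE, na = "n/a")
  invisible(path)
}
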