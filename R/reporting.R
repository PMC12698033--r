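#' @title Screening reports
#' @description Render screening results as a reviewable checklist report:
#'   per-criterion status with role, a relevant-document list (the "red dot"
#'   set), and document bodies with concept mentions highlighted. Affirmed
#'   and negated mentions are styled distinctly; the legend says so. Output
#'   is deterministic for fixed input: a machine-readable JSON result plus
#'   Markdown and self-contained HTML documents.
#' @name reporting
NULL

#' Split a document into highlighted segments
#'
#' Partitions the document text into an ordered list of segments; every
#' annotation span becomes a highlighted segment carrying its annotation
#' reference. Concatenating the segment texts reproduces the original text
#' byte-for-byte.
#'
#' @param doc a [clinical_document()].
#' @param annotations annotation data frame for this document, spans
#'   non-overlapping (the tagger guarantees this).
#' @return object of class `highlighted_document`: list with `doc_id` and
#'   `segments`, each segment `list(text, highlighted, ref)` where `ref` is
#'   `NULL` or `list(start, end, cui, negated)`.
#' @export
highlight_document <- function(doc, annotations) {
  stopifnot(inherits(doc, "clinical_document"))
  text <- doc$text
  ann <- annotations[annotations$doc_id == doc$doc_id, , drop = FALSE]
  ann <- ann[order(ann$start), , drop = FALSE]
  if (nrow(ann) > 1L && any(ann$start[-1L] < ann$end[-nrow(ann)]))
    stop("overlapping annotation spans in document ", doc$doc_id,
         call. = FALSE)
  if (nrow(ann) && (min(ann$start) < 0L || max(ann$end) > nchar(text)))
    stop("annotation span outside document ", doc$doc_id, call. = FALSE)
  segments <- list()
  pos <- 0L
  for (i in seq_len(nrow(ann))) {
    if (ann$start[i] > pos) {
      segments[[length(segments) + 1L]] <-
        list(text = substring(text, pos + 1L, ann$start[i]),
             highlighted = FALSE, ref = NULL)
    }
    segments[[length(segments) + 1L]] <-
      list(text = substring(text, ann$start[i] + 1L, ann$end[i]),
           highlighted = TRUE,
           ref = list(start = ann$start[i], end = ann$end[i],
                      cui = ann$cui[i], negated = ann$negated[i]))
    pos <- ann$end[i]
  }
  if (pos < nchar(text) || !length(segments)) {
    segments[[length(segments) + 1L]] <-
      list(text = substring(text, pos + 1L, nchar(text)),
           highlighted = FALSE, ref = NULL)
  }
  structure(list(doc_id = doc$doc_id, segments = segments),
            class = "highlighted_document")
}

#' Reassemble original text from a highlighted document
#' @param hd a `highlighted_document`.
#' @return the original document text.
#' @export
dehighlight <- function(hd) {
  paste(vapply(hd$segments, function(s) s$text, character(1)), collapse = "")
}

status_glyph <- function(status, role) {
  base <- c(MET = "yes", NOT_MET = "no", UNKNOWN = "no (needs review)")[status]
  base
}

md_escape <- function(s) gsub("([\\\\`*_{}|])", "\\\\\\1", s)

html_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

segment_md <- function(s) {
  if (!s$highlighted) return(s$text)
  if (isTRUE(s$ref$negated)) paste0("~~", s$text, "~~")
  else paste0("**", s$text, "**")
}

segment_html <- function(s, doc_id) {
  if (!s$highlighted) return(html_escape(s$text))
  cls <- if (isTRUE(s$ref$negated)) "negated" else "affirmed"
  sprintf('<mark class="%s" id="ev-%s-%d">%s</mark>',
          cls, doc_id, s$ref$start, html_escape(s$text))
}

#' Render a screening report
#'
#' Emits (a) the machine-readable result JSON, (b) a Markdown report and
#' (c) a self-contained HTML report, each listing every criterion with its
#' status and role, the relevant-document list flagged, and highlighted
#' document bodies appended. Affirmed mentions are bold `<mark>`s, negated
#' mentions struck through; `UNKNOWN` verdicts render as "no (needs
#' review)". Evidence referencing a document id absent from the record is an
#' error.
#'
#' @param result a `screening_result`.
#' @param record the [patient_record()] the result refers to.
#' @param annotations output of [annotate_record()].
#' @param dir output directory; files `result.json`, `report.md`,
#'   `report.html` are written there.
#' @return named character vector of file paths, invisibly.
#' @export
render_report <- function(result, record, annotations, dir) {
  stopifnot(inherits(result, "screening_result"))
  doc_ids <- vapply(record$documents, function(d) d$doc_id, character(1))
  for (v in result$verdicts) {
    for (e in v$evidence) {
      if (identical(e$type, "annotation") && !(e$doc_id %in% doc_ids))
        stop("dangling evidence reference: document ", e$doc_id,
             " is not in the record", call. = FALSE)
    }
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  serialize_result(result, file.path(dir, "result.json"))

  flagged <- result$relevant_docs
  ann <- if (is.data.frame(annotations)) annotations else annotations
  hl <- lapply(record$documents[doc_ids %in% flagged], function(d) {
    a <- if (is.data.frame(ann)) ann[ann$doc_id == d$doc_id, , drop = FALSE]
    else ann[[d$doc_id]]
    highlight_document(d, a)
  })
  names(hl) <- doc_ids[doc_ids %in% flagged]

  # Markdown ---------------------------------------------------------------
  md <- c(sprintf("# Eligibility screening report"),
          "",
          sprintf("- Patient: `%s`", result$patient_id),
          sprintf("- Trial: %s (checklist version %s)",
                  md_escape(result$trial_name), result$checklist_version),
          "",
          "## Checklist", "",
          "| # | Criterion | Role | Verdict |",
          "|---|-----------|------|---------|")
  for (i in seq_along(result$verdicts)) {
    v <- result$verdicts[[i]]
    md <- c(md, sprintf("| %d | %s | %s | %s |", i,
                        md_escape(v$criterion_label), tolower(v$role),
                        status_glyph(v$status, v$role)))
  }
  md <- c(md, "", "## Documents", "")
  for (d in record$documents) {
    mark <- if (d$doc_id %in% flagged) "●" else "○"
    md <- c(md, sprintf("- %s `%s` (%s, %s)%s", mark, d$doc_id, d$doc_type,
                        format_timestamp(d$timestamp),
                        if (d$doc_id %in% flagged)
                          " — contains relevant information" else ""))
  }
  md <- c(md, "",
          "Legend: ● relevant document; **bold** affirmed mention; ~~struck~~ negated mention.",
          "")
  for (id in names(hl)) {
    md <- c(md, sprintf("### Document `%s`", id), "",
            paste(vapply(hl[[id]]$segments, segment_md, character(1)),
                  collapse = ""), "")
  }
  writeLines(md, file.path(dir, "report.md"), useBytes = TRUE)

  # HTML -------------------------------------------------------------------
  h <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
         "<style>",
         "mark.affirmed{background:#ffe08a;font-weight:bold}",
         "mark.negated{background:#d8d8d8;text-decoration:line-through}",
         "td,th{border:1px solid #999;padding:4px 8px}table{border-collapse:collapse}",
         ".dot{color:#c00}",
         "</style></head><body>",
         "<h1>Eligibility screening report</h1>",
         sprintf("<p>Patient: <code>%s</code><br>Trial: %s (checklist version %s)</p>",
                 html_escape(result$patient_id),
                 html_escape(result$trial_name),
                 html_escape(result$checklist_version)),
         "<h2>Checklist</h2>",
         "<table><tr><th>#</th><th>Criterion</th><th>Role</th><th>Verdict</th><th>Evidence</th></tr>")
  for (i in seq_along(result$verdicts)) {
    v <- result$verdicts[[i]]
    links <- vapply(Filter(function(e) identical(e$type, "annotation"),
                           v$evidence), function(e) {
      sprintf('<a href="#ev-%s-%d">%s</a>', e$doc_id, e$start,
              html_escape(e$doc_id))
    }, character(1))
    h <- c(h, sprintf("<tr><td>%d</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>",
                      i, html_escape(v$criterion_label), tolower(v$role),
                      status_glyph(v$status, v$role),
                      paste(unique(links), collapse = " ")))
  }
  h <- c(h, "</table>", "<h2>Documents</h2>", "<ul>")
  for (d in record$documents) {
    dot <- if (d$doc_id %in% flagged) '<span class="dot">●</span> ' else ""
    h <- c(h, sprintf("<li>%s<code>%s</code> (%s, %s)</li>", dot,
                      html_escape(d$doc_id), html_escape(d$doc_type),
                      format_timestamp(d$timestamp)))
  }
  h <- c(h, "</ul>",
         "<p>Legend: <span class=\"dot\">●</span> relevant document; <mark class=\"affirmed\">affirmed mention</mark>; <mark class=\"negated\">negated mention</mark>.</p>")
  for (id in names(hl)) {
    body <- paste(vapply(hl[[id]]$segments, segment_html, character(1),
                         doc_id = id), collapse = "")
    h <- c(h, sprintf("<h3>Document <code>%s</code></h3>", html_escape(id)),
           sprintf("<pre style=\"white-space:pre-wrap\">%s</pre>", body))
  }
  h <- c(h, "</body></html>")
  writeLines(h, file.path(dir, "report.html"), useBytes = TRUE)

  invisible(c(result = file.path(dir, "result.json"),
              markdown = file.path(dir, "report.md"),
              html = file.path(dir, "report.html")))
}
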