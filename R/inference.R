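#' @title Eligibility inference engine
#' @description Evaluates checklist criteria against a patient's lab series
#'   and extracted concept annotations, producing evidence-linked verdicts.
#'   Verdicts are three-valued — `MET`, `NOT_MET`, `UNKNOWN` — combined with
#'   strong-Kleene logic: missing labs and empty windows are epistemically
#'   different from negative findings, and silently coercing missing data to
#'   "no" is exactly the failure mode a screening tool must avoid. Absence of
#'   affirmed mentions is `NOT_MET` for concept criteria (closed-world at the
#'   leaf); `UNKNOWN` is reserved for structural failures (no in-window lab,
#'   missing control value in ratio mode, no documents of the requested types
#'   at all).
#' @name inference
NULL

STATUSES <- c("MET", "NOT_MET", "UNKNOWN")

#' Strong-Kleene combinators over verdict statuses
#'
#' `AND` is `MET` iff all children are `MET`, `NOT_MET` if any child is
#' `NOT_MET`, else `UNKNOWN`; `OR` is the dual; `NOT` swaps `MET`/`NOT_MET`
#' and fixes `UNKNOWN`.
#'
#' @param statuses character vector of statuses.
#' @param status single status.
#' @return a single status.
#' @export
kleene_and <- function(statuses) {
  if (any(statuses == "NOT_MET")) "NOT_MET"
  else if (all(statuses == "MET")) "MET"
  else "UNKNOWN"
}

#' @rdname kleene_and
#' @export
kleene_or <- function(statuses) {
  if (any(statuses == "MET")) "MET"
  else if (all(statuses == "NOT_MET")) "NOT_MET"
  else "UNKNOWN"
}

#' @rdname kleene_and
#' @export
kleene_not <- function(status) {
  switch(status, MET = "NOT_MET", NOT_MET = "MET", "UNKNOWN")
}

new_verdict <- function(label, role, status, evidence, explanation) {
  structure(list(criterion_label = label, role = role, status = status,
                 evidence = evidence, explanation = explanation),
            class = "criterion_verdict")
}

lab_evidence <- function(lr) {
  list(type = "lab", row = lr$row, item = lr$item, value = lr$value,
       timestamp = format_timestamp(lr$timestamp))
}

annotation_evidence <- function(ann_row) {
  list(type = "annotation", doc_id = ann_row$doc_id,
       start = ann_row$start, end = ann_row$end, cui = ann_row$cui,
       matched_text = ann_row$matched_text)
}

comparator_fun <- function(comparator) {
  switch(comparator, LT = `<`, LE = `<=`, GT = `>`, GE = `>=`, EQ = `==`)
}

comparator_symbol <- function(comparator) {
  c(LT = "<", LE = "<=", GT = ">", GE = ">=", EQ = "=")[comparator]
}

#' Evaluate a lab criterion
#'
#' Selects the most recent in-window result for the criterion's lab item
#' ([latest_lab()]); `ABSOLUTE` mode compares the value, `RATIO_TO_CONTROL`
#' compares `value / control_value`, against the threshold under the
#' criterion's comparator. No in-window result, or a missing control value in
#' ratio mode, yields `UNKNOWN` with an explanation.
#'
#' @param crit a [lab_criterion()].
#' @param record a [patient_record()].
#' @return a `criterion_verdict`.
#' @export
eval_lab_criterion <- function(crit, record) {
  lr <- latest_lab(record, crit$lab_item$code, crit$window)
  label <- crit$criterion_id
  if (is.null(lr))
    return(new_verdict(label, NA_character_, "UNKNOWN", list(),
                       sprintf("no in-window result for lab '%s'",
                               crit$lab_item$name)))
  if (crit$mode == "RATIO_TO_CONTROL") {
    if (is.na(lr$control_value))
      return(new_verdict(label, NA_character_, "UNKNOWN", list(),
                         sprintf("lab '%s' result at %s lacks a control value for ratio comparison",
                                 crit$lab_item$name,
                                 format_timestamp(lr$timestamp))))
    observed <- lr$value / lr$control_value
    desc <- sprintf("%s/control = %.4g", crit$lab_item$name, observed)
  } else {
    observed <- lr$value
    desc <- sprintf("%s = %.4g", crit$lab_item$name, observed)
  }
  ok <- comparator_fun(crit$comparator)(observed, crit$threshold)
  status <- if (ok) "MET" else "NOT_MET"
  new_verdict(label, NA_character_, status, list(lab_evidence(lr)),
              sprintf("%s %s %s %s", desc,
                      if (ok) "satisfies" else "fails",
                      comparator_symbol(crit$comparator),
                      fmt_num(crit$threshold)))
}

#' Evaluate a concept criterion
#'
#' `MET` iff at least one non-negated annotation whose CUI is among the
#' criterion's concepts lies in a document of an allowed type with a
#' timestamp inside the window; evidence lists every qualifying annotation.
#' `NOT_MET` when no qualifying affirmed annotation exists; `UNKNOWN` when
#' the record contains no documents of the requested types at all.
#'
#' @param crit a [concept_criterion()].
#' @param record a [patient_record()].
#' @param annotations output of [annotate_record()] (or a combined frame).
#' @return a `criterion_verdict`.
#' @export
eval_concept_criterion <- function(crit, record, annotations) {
  label <- crit$criterion_id
  doc_types_present <- vapply(record$documents, function(d) d$doc_type,
                              character(1))
  if (!any(doc_types_present %in% crit$doc_types))
    return(new_verdict(label, NA_character_, "UNKNOWN", list(),
                       sprintf("record has no documents of type(s) %s",
                               paste(crit$doc_types, collapse = ", "))))
  ann <- combine_annotations(annotations)
  qualifying <- integer(0)
  if (nrow(ann)) {
    doc_type_of <- structure(doc_types_present,
                             names = vapply(record$documents,
                                            function(d) d$doc_id, character(1)))
    ok <- !ann$negated & ann$cui %in% crit$concepts$cui &
      doc_type_of[ann$doc_id] %in% crit$doc_types &
      in_window(ann$doc_timestamp, crit$window, record$index_time)
    qualifying <- which(!is.na(ok) & ok)
  }
  if (length(qualifying)) {
    ev <- lapply(qualifying, function(i) annotation_evidence(ann[i, ]))
    new_verdict(label, NA_character_, "MET", ev,
                sprintf("%d affirmed mention(s) of %s in qualifying documents",
                        length(qualifying),
                        paste(crit$concepts$preferred_name, collapse = "/")))
  } else {
    new_verdict(label, NA_character_, "NOT_MET", list(),
                sprintf("no affirmed in-window mention of %s in documents of type(s) %s",
                        paste(crit$concepts$preferred_name, collapse = "/"),
                        paste(crit$doc_types, collapse = ", ")))
  }
}

#' Evaluate a rule expression
#'
#' Leaves via [eval_lab_criterion()] / [eval_concept_criterion()];
#' combinators via strong-Kleene three-valued logic. Evidence is the union
#' of the children whose status contributed to the combined status.
#'
#' @param expr a validated `rule_expr`.
#' @param record a [patient_record()].
#' @param annotations output of [annotate_record()].
#' @return a `criterion_verdict`.
#' @export
eval_expr <- function(expr, record, annotations) {
  kind <- expr$kind
  if (kind == "LAB") return(eval_lab_criterion(expr$payload, record))
  if (kind == "CONCEPT")
    return(eval_concept_criterion(expr$payload, record, annotations))
  child_v <- lapply(expr$children, eval_expr, record = record,
                    annotations = annotations)
  statuses <- vapply(child_v, function(v) v$status, character(1))
  if (kind == "NOT") {
    v <- child_v[[1L]]
    return(new_verdict("NOT", NA_character_, kleene_not(v$status),
                       v$evidence, paste0("not(", v$explanation, ")")))
  }
  status <- if (kind == "AND") kleene_and(statuses) else kleene_or(statuses)
  contributing <- switch(
    status,
    MET = if (kind == "AND") seq_along(child_v) else which(statuses == "MET"),
    NOT_MET = if (kind == "AND") which(statuses == "NOT_MET")
    else seq_along(child_v),
    which(statuses != "UNKNOWN"))
  ev <- do.call(c, c(list(list()), lapply(child_v[contributing],
                                          function(v) v$evidence)))
  new_verdict(kind, NA_character_, status, ev,
              paste0(tolower(kind), "(",
                     paste(statuses, collapse = ", "), ") -> ", status))
}

#' Screen one patient against a checklist
#'
#' One verdict per checklist item, in checklist order; `relevant_docs` is
#' the union of document ids cited by any verdict's evidence (the report's
#' "relevant information" flags). Deterministic for fixed inputs.
#'
#' @param cl an `eligibility_checklist`.
#' @param record a [patient_record()].
#' @param annotations output of [annotate_record()].
#' @return object of class `screening_result` with fields `patient_id`,
#'   `trial_name`, `checklist_version`, `verdicts`, `relevant_docs`.
#' @export
screen_patient <- function(cl, record, annotations) {
  stopifnot(inherits(cl, "eligibility_checklist"),
            inherits(record, "patient_record"))
  verdicts <- lapply(cl$items, function(it) {
    v <- eval_expr(it$expr, record, annotations)
    new_verdict(it$label, it$role, v$status, v$evidence, v$explanation)
  })
  doc_ids <- unlist(lapply(verdicts, function(v) {
    vapply(Filter(function(e) e$type == "annotation", v$evidence),
           function(e) e$doc_id, character(1))
  }))
  structure(list(patient_id = record$patient_id,
                 trial_name = cl$trial_name,
                 checklist_version = cl$version,
                 verdicts = verdicts,
                 relevant_docs = sort(unique(doc_ids))),
            class = "screening_result")
}

#' Serialize a screening result to JSON
#'
#' @param result a `screening_result`.
#' @param path optional file path; when omitted the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
serialize_result <- function(result, path = NULL) {
  doc <- list(patient_id = result$patient_id,
              trial_name = result$trial_name,
              checklist_version = result$checklist_version,
              verdicts = lapply(result$verdicts, function(v) {
                list(criterion_label = v$criterion_label, role = v$role,
                     status = v$status, evidence = v$evidence,
                     explanation = v$explanation)
              }),
              relevant_docs = as.list(result$relevant_docs))
  json <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                        pretty = TRUE, null = "null"))
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(json))
  }
  json
}
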