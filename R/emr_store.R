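#' @title Patient record bundles
#' @description Model and read/write patient record bundles: timestamped,
#'   typed clinical documents (JSONL) plus a structured lab-result series
#'   (CSV), tied together by a small JSON manifest carrying the patient id
#'   and the index time from which temporal windows are measured.
#' @name emr_store
NULL

#' Clinical document
#'
#' @param doc_id identifier, unique within a record.
#' @param doc_type document-type label (e.g. "admission note",
#'   "outpatient note", "discharge summary").
#' @param timestamp ISO-8601 string or `POSIXct`.
#' @param text UTF-8 narrative.
#' @return object of class `clinical_document`.
#' @export
clinical_document <- function(doc_id, doc_type, timestamp, text) {
  structure(list(doc_id = as.character(doc_id),
                 doc_type = as.character(doc_type),
                 timestamp = parse_timestamp(timestamp),
                 text = as.character(text)),
            class = "clinical_document")
}

#' Lab result table
#'
#' Canonical constructor for the lab series: one row per result.
#' `control_value` is the control denominator for ratio-to-control criteria
#' (e.g. the control APTT); `NA` when the feed omits it.
#'
#' @param item lab item code/name.
#' @param value numeric result, finite.
#' @param unit unit string ("" allowed).
#' @param control_value numeric or `NA`.
#' @param timestamp ISO-8601 strings or `POSIXct`.
#' @return data frame with class `lab_table`.
#' @export
lab_table <- function(item = character(0), value = numeric(0),
                      unit = character(0), control_value = numeric(0),
                      timestamp = character(0)) {
  value <- as.numeric(value)
  control_value <- as.numeric(control_value)
  if (length(value) && any(!is.finite(value)))
    stop("lab values must be finite", call. = FALSE)
  if (any(!is.na(control_value) & control_value <= 0))
    stop("control_value must be > 0 when present", call. = FALSE)
  ts <- if (length(timestamp)) parse_timestamp(timestamp)
  else as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC")
  df <- data.frame(item = as.character(item), value = value,
                   unit = as.character(unit), control_value = control_value,
                   timestamp = ts, stringsAsFactors = FALSE)
  class(df) <- c("lab_table", "data.frame")
  df
}

#' Patient record
#'
#' @param patient_id non-empty identifier.
#' @param index_time the reference time point (e.g. triage) from which
#'   temporal windows are measured; ISO-8601 or `POSIXct`.
#' @param documents list of [clinical_document()]s with unique `doc_id`s.
#' @param labs a [lab_table()].
#' @return object of class `patient_record`.
#' @export
patient_record <- function(patient_id, index_time, documents = list(),
                           labs = lab_table()) {
  patient_id <- as.character(patient_id)
  if (!nzchar(patient_id)) stop("patient_id must be non-empty", call. = FALSE)
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate doc_id: ", ids[duplicated(ids)][1], call. = FALSE)
  if (!inherits(labs, "lab_table")) {
    labs <- lab_table(labs$item, labs$value, labs$unit, labs$control_value,
                      labs$timestamp)
  }
  structure(list(patient_id = patient_id,
                 index_time = parse_timestamp(index_time),
                 documents = documents, labs = labs),
            class = "patient_record")
}

#' Write a patient record bundle to a directory
#'
#' Layout: `manifest.json` (patient_id, index_time, file names),
#' `documents.jsonl` (one document per line) and `labs.csv`.
#'
#' @param record a `patient_record`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(record, dir) {
  stopifnot(inherits(record, "patient_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(patient_id = record$patient_id,
                   index_time = format_timestamp(record$index_time),
                   documents_file = "documents.jsonl",
                   labs_file = "labs.csv")
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           pretty = TRUE)),
             file.path(dir, "manifest.json"), useBytes = TRUE)
  doc_lines <- vapply(record$documents, function(d) {
    as.character(jsonlite::toJSON(
      list(doc_id = d$doc_id, doc_type = d$doc_type,
           timestamp = format_timestamp(d$timestamp), text = d$text),
      auto_unbox = TRUE))
  }, character(1))
  writeLines(doc_lines, file.path(dir, "documents.jsonl"), useBytes = TRUE)
  labs <- record$labs
  out <- data.frame(item = labs$item, value = labs$value, unit = labs$unit,
                    control_value = labs$control_value,
                    timestamp = if (nrow(labs)) format_timestamp(labs$timestamp)
                    else character(0),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, file.path(dir, "labs.csv"), row.names = FALSE,
                   na = "")
  invisible(dir)
}

#' Read a patient record bundle from a directory
#'
#' Errors name the offending line (malformed JSONL), id (duplicate doc_id)
#' or value (unparseable timestamp).
#'
#' @param dir bundle directory containing `manifest.json`.
#' @return a `patient_record`.
#' @export
read_bundle <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::fromJSON(mpath, simplifyVector = TRUE)
  lines <- readLines(file.path(dir, manifest$documents_file), warn = FALSE,
                     encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  documents <- lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed document record at line ", i, ": ",
                         conditionMessage(e), call. = FALSE))
    for (f in c("doc_id", "doc_type", "timestamp", "text"))
      if (is.null(x[[f]]))
        stop("malformed document record at line ", i, ": missing field ", f,
             call. = FALSE)
    clinical_document(x$doc_id, x$doc_type, x$timestamp, x$text)
  })
  lpath <- file.path(dir, manifest$labs_file)
  raw <- utils::read.csv(lpath, stringsAsFactors = FALSE,
                         colClasses = c(item = "character", value = "numeric",
                                        unit = "character",
                                        control_value = "numeric",
                                        timestamp = "character"),
                         na.strings = "")
  raw$unit[is.na(raw$unit)] <- ""
  labs <- lab_table(raw$item, raw$value, raw$unit, raw$control_value,
                    raw$timestamp)
  patient_record(manifest$patient_id, manifest$index_time, documents, labs)
}

#' Select documents by type and window
#'
#' A pure filter: returns exactly the documents whose `doc_type` is in
#' `doc_types` and whose timestamp falls in the resolved window (all matching
#' documents when `window` is `NULL`), in stable order by timestamp then
#' `doc_id`.
#'
#' @param record a `patient_record`.
#' @param doc_types non-empty character vector.
#' @param window optional [temporal_window()].
#' @return list of `clinical_document`s.
#' @export
select_documents <- function(record, doc_types, window = NULL) {
  stopifnot(length(doc_types) >= 1L)
  docs <- record$documents
  if (!length(docs)) return(list())
  keep <- vapply(docs, function(d) {
    d$doc_type %in% doc_types &&
      in_window(d$timestamp, window, record$index_time)
  }, logical(1))
  docs <- docs[keep]
  if (!length(docs)) return(list())
  ts <- vapply(docs, function(d) as.numeric(d$timestamp), numeric(1))
  ids <- vapply(docs, function(d) d$doc_id, character(1))
  docs[order(ts, ids)]
}

#' Most recent in-window lab result
#'
#' Returns the most recent result for `item` inside the window (`NULL`
#' window means any time up to and including all results). Timestamp ties
#' are broken by input order, last row wins. Returns `NULL` when no
#' in-window result exists.
#'
#' @param record a `patient_record`.
#' @param item lab item code/name to match against the `item` column.
#' @param window optional [temporal_window()].
#' @return a list with the result row's fields plus `row` (its index in
#'   `record$labs`), or `NULL`.
#' @export
latest_lab <- function(record, item, window = NULL) {
  labs <- record$labs
  idx <- which(labs$item == item &
                 in_window(labs$timestamp, window, record$index_time))
  if (!length(idx)) return(NULL)
  ts <- as.numeric(labs$timestamp[idx])
  best <- idx[ts == max(ts)]
  i <- best[length(best)]  # tie: last in input order wins
  list(row = i, item = labs$item[i], value = labs$value[i],
       unit = labs$unit[i], control_value = labs$control_value[i],
       timestamp = labs$timestamp[i])
}
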