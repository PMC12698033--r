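#' @title Lexicon-based clinical concept tagger
#' @description Deterministic concept extraction: a lexicon maps surface
#'   forms (synonyms, acronyms, abbreviations) to concept unique identifiers
#'   (CUIs) and semantic types; matching is greedy longest-match,
#'   left-to-right, non-overlapping and token-boundary aware; trigger/scope
#'   rules flag mentions under negation ("no history of head injury").
#'   Broad classes (e.g. Anticoagulant) are one CUI with many drug-name
#'   surface forms. The tagger sits behind a pluggable extractor contract:
#'   anything producing the [annotate_record()] mapping can be substituted
#'   downstream.
#' @name concept_tagger
NULL

#' Construct a concept lexicon
#'
#' @param entries data frame with columns `cui`, `preferred_name`,
#'   `semantic_types` (pipe-separated labels), `surface_form`,
#'   `case_sensitive` (logical); one row per (CUI, surface form). Rows of one
#'   CUI must agree on `preferred_name` and `semantic_types`; the order of
#'   first appearance defines declaration order for ambiguity resolution.
#' @return data frame with class `concept_lexicon`.
#' @export
lexicon <- function(entries) {
  req <- c("cui", "preferred_name", "semantic_types", "surface_form",
           "case_sensitive")
  stopifnot(is.data.frame(entries), all(req %in% names(entries)))
  df <- data.frame(cui = as.character(entries$cui),
                   preferred_name = as.character(entries$preferred_name),
                   semantic_types = as.character(entries$semantic_types),
                   surface_form = as.character(entries$surface_form),
                   case_sensitive = as.logical(entries$case_sensitive),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$surface_form)))
    stop("lexicon surface forms must be non-empty", call. = FALSE)
  for (cui in unique(df$cui)) {
    rows <- df[df$cui == cui, ]
    if (length(unique(rows$preferred_name)) != 1L)
      stop("lexicon entry ", cui, " has conflicting preferred names",
           call. = FALSE)
  }
  class(df) <- c("concept_lexicon", "data.frame")
  df
}

#' @rdname lexicon
#' @param path CSV path with the columns above.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cui = "character",
                                       preferred_name = "character",
                                       semantic_types = "character",
                                       surface_form = "character",
                                       case_sensitive = "logical"))
  lexicon(df)
}

#' @rdname lexicon
#' @param lex a `concept_lexicon`.
#' @export
write_lexicon <- function(lex, path) {
  utils::write.csv(as.data.frame(lex), path, row.names = FALSE)
  invisible(path)
}

first_semantic_type <- function(semtypes) {
  vapply(strsplit(semtypes, "|", fixed = TRUE), `[[`, character(1), 1L)
}

# Look a display name up by preferred name or surface form (case-insensitive).
lexicon_lookup_name <- function(lex, name) {
  lname <- tolower(name)
  hit <- which(tolower(lex$preferred_name) == lname |
                 tolower(lex$surface_form) == lname)
  if (!length(hit)) return(NULL)
  i <- hit[1L]
  list(cui = lex$cui[i], preferred_name = lex$preferred_name[i])
}

#' Tokenize text with character offsets
#'
#' Unicode word tokenization; hyphenated terms are single tokens; sentence
#' punctuation (`.` `;` `:` `!` `?` `,`) is emitted as its own token so
#' negation scopes can end at it. Offsets are 0-based half-open.
#'
#' @param text a single string.
#' @return data frame with columns `token`, `start`, `end`.
#' @export
tokenize <- function(text) {
  m <- gregexpr("[\\p{L}\\p{N}][\\p{L}\\p{N}'_-]*|[.;:!?,]", text, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  len <- attr(m, "match.length")
  data.frame(token = substring(text, m, m + len - 1L),
             start = as.integer(m - 1L), end = as.integer(m - 1L + len),
             stringsAsFactors = FALSE)
}

rx_escape <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)

# boundary assertions: no letter/digit/hyphen/underscore adjacent
form_pattern <- function(form) {
  core <- gsub("\\s+", "\\\\s+", rx_escape(form))
  paste0("(?<![\\p{L}\\p{N}_-])", core, "(?![\\p{L}\\p{N}_-])")
}

#' Tag a document against a lexicon
#'
#' Greedy longest-match, left-to-right, non-overlapping; token-boundary
#' aware; case-insensitive unless a form is flagged case-sensitive. An
#' ambiguous surface form (declared under several CUIs) maps to its
#' first-declared entry, with a warning. All annotations start
#' `negated = FALSE`; run [detect_negation()] afterwards.
#'
#' @param doc a [clinical_document()].
#' @param lex a [lexicon()].
#' @return annotation data frame with columns `doc_id`, `start`, `end`
#'   (0-based half-open), `matched_text`, `cui`, `preferred_name`,
#'   `semantic_type`, `negated`, `doc_timestamp`.
#' @export
tag_document <- function(doc, lex) {
  stopifnot(inherits(doc, "clinical_document"))
  text <- doc$text
  empty <- data.frame(doc_id = character(0), start = integer(0),
                      end = integer(0), matched_text = character(0),
                      cui = character(0), preferred_name = character(0),
                      semantic_type = character(0), negated = logical(0),
                      stringsAsFactors = FALSE)
  empty$doc_timestamp <- as.POSIXct(numeric(0), origin = "1970-01-01",
                                    tz = "UTC")
  if (!nzchar(text) || !nrow(lex)) return(empty)
  # first-declared entry wins for an ambiguous surface form
  key <- paste0(tolower(lex$surface_form), "\r", lex$case_sensitive)
  first <- !duplicated(key)
  dups <- !first & lex$cui != lex$cui[match(key, key)]
  if (any(dups))
    warning("ambiguous surface form(s) mapped to first-declared entry: ",
            paste(unique(lex$surface_form[dups]), collapse = ", "),
            call. = FALSE)
  forms <- lex[first, , drop = FALSE]
  cand <- list()
  for (i in seq_len(nrow(forms))) {
    pat <- form_pattern(forms$surface_form[i])
    m <- gregexpr(pat, text, perl = TRUE,
                  ignore.case = !forms$case_sensitive[i])[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    cand[[length(cand) + 1L]] <-
      data.frame(start = as.integer(m - 1L), end = as.integer(m - 1L + len),
                 row = i, stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, -(cand$end - cand$start), cand$row), ,
               drop = FALSE]
  cursor <- 0L
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= cursor) {
      keep[i] <- TRUE
      cursor <- cand$end[i]
    }
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  out <- data.frame(
    doc_id = doc$doc_id, start = cand$start, end = cand$end,
    matched_text = substring(text, cand$start + 1L, cand$end),
    cui = forms$cui[cand$row],
    preferred_name = forms$preferred_name[cand$row],
    semantic_type = first_semantic_type(forms$semantic_types[cand$row]),
    negated = FALSE, stringsAsFactors = FALSE)
  out$doc_timestamp <- rep(doc$timestamp, nrow(out))
  rownames(out) <- NULL
  out
}

#' Filter annotations by semantic type
#'
#' Discards annotations whose semantic type is not in `allowed`, preserving
#' order — the counterpart of an NLP engine's semantic-type settings.
#'
#' @param annotations annotation data frame from [tag_document()].
#' @param allowed character vector of allowed semantic-type labels.
#' @return filtered annotation data frame.
#' @export
filter_semantic_types <- function(annotations, allowed) {
  out <- annotations[annotations$semantic_type %in% allowed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Negation rule set
#'
#' @param pre_triggers phrases scoping forward over following tokens
#'   (e.g. "no", "denies", "no history of").
#' @param post_triggers phrases scoping backward (e.g. "was ruled out").
#' @param terminators tokens that end a scope (e.g. "but", ".").
#' @param scope_window maximum number of tokens a trigger reaches.
#' @return object of class `negation_rules`.
#' @export
negation_rules <- function(pre_triggers, post_triggers = character(0),
                           terminators = character(0), scope_window = 6L) {
  scope_window <- as.integer(scope_window)
  if (length(pre_triggers) < 1L && length(post_triggers) < 1L)
    stop("at least one trigger is required", call. = FALSE)
  if (is.na(scope_window) || scope_window < 1L)
    stop("scope_window must be >= 1", call. = FALSE)
  structure(list(pre_triggers = as.character(pre_triggers),
                 post_triggers = as.character(post_triggers),
                 terminators = as.character(terminators),
                 scope_window = scope_window),
            class = "negation_rules")
}

#' @rdname negation_rules
#' @param path JSON file with fields pre_triggers, post_triggers,
#'   terminators, scope_window.
#' @export
read_negation_rules <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  negation_rules(x$pre_triggers, x$post_triggers, x$terminators,
                 x$scope_window)
}

#' @rdname negation_rules
#' @param rules a `negation_rules` object.
#' @export
write_negation_rules <- function(rules, path) {
  writeLines(as.character(jsonlite::toJSON(unclass(rules), pretty = TRUE,
                                           auto_unbox = FALSE)),
             path, useBytes = TRUE)
  invisible(path)
}

# token sequences (lowercased) for each trigger phrase
trigger_tokens <- function(phrases) {
  lapply(phrases, function(p) tolower(tokenize(p)$token))
}

# does phrase (token vector) occur ending at position `at` in tokens?
phrase_ends_at <- function(tokens_lc, phrase, at) {
  k <- length(phrase)
  if (at < k) return(FALSE)
  all(tokens_lc[(at - k + 1L):at] == phrase)
}

phrase_starts_at <- function(tokens_lc, phrase, at) {
  k <- length(phrase)
  if (at + k - 1L > length(tokens_lc)) return(FALSE)
  all(tokens_lc[at:(at + k - 1L)] == phrase)
}

#' Detect negated concept mentions
#'
#' An annotation is flagged negated iff a pre-trigger ends within
#' `scope_window` tokens before it with no terminator token in between, or a
#' post-trigger starts within `scope_window` tokens after it with no
#' terminator in between. Deterministic.
#'
#' @param doc_text the document text the annotations were produced from.
#' @param annotations annotation data frame (same document).
#' @param rules a [negation_rules()].
#' @return the annotations with the `negated` column set.
#' @export
detect_negation <- function(doc_text, annotations, rules) {
  if (!nrow(annotations)) return(annotations)
  stopifnot(inherits(rules, "negation_rules"))
  toks <- tokenize(doc_text)
  toks_lc <- tolower(toks$token)
  term <- tolower(rules$terminators)
  pre <- trigger_tokens(rules$pre_triggers)
  post <- trigger_tokens(rules$post_triggers)
  w <- rules$scope_window
  is_term <- toks_lc %in% term
  negated <- logical(nrow(annotations))
  for (a in seq_len(nrow(annotations))) {
    # token indices strictly before / after the annotation span
    before <- which(toks$end <= annotations$start[a])
    after <- which(toks$start >= annotations$end[a])
    hit <- FALSE
    if (length(before)) {
      last <- before[length(before)]
      lo <- max(1L, last - w + 1L)
      for (p in pre) {
        if (hit) break
        for (at in last:lo) {
          if (!phrase_ends_at(toks_lc, p, at)) next
          gap <- if (at < last) seq.int(at + 1L, last) else integer(0)
          if (!any(is_term[gap])) { hit <- TRUE; break }
        }
      }
    }
    if (!hit && length(after) && length(post)) {
      first <- after[1L]
      hi <- min(length(toks_lc), first + w - 1L)
      for (p in post) {
        if (hit) break
        for (at in first:hi) {
          if (!phrase_starts_at(toks_lc, p, at)) next
          gap <- if (at > first) seq.int(first, at - 1L) else integer(0)
          if (!any(is_term[gap])) { hit <- TRUE; break }
        }
      }
    }
    negated[a] <- hit
  }
  annotations$negated <- negated
  annotations
}

#' Annotate every document of a record
#'
#' The full extraction pipeline per document: tag, filter by semantic type
#' (skipped when `allowed_types` is `NULL`), detect negation (skipped when
#' `rules` is `NULL`). Annotations carry their document timestamps for
#' downstream temporal logic.
#'
#' @param record a [patient_record()].
#' @param lex a [lexicon()].
#' @param allowed_types optional character vector of semantic types to keep.
#' @param rules optional [negation_rules()].
#' @return named list mapping `doc_id` to annotation data frames.
#' @export
annotate_record <- function(record, lex, allowed_types = NULL, rules = NULL) {
  out <- lapply(record$documents, function(doc) {
    ann <- tag_document(doc, lex)
    if (!is.null(allowed_types))
      ann <- filter_semantic_types(ann, allowed_types)
    if (!is.null(rules)) ann <- detect_negation(doc$text, ann, rules)
    ann
  })
  names(out) <- vapply(record$documents, function(d) d$doc_id, character(1))
  out
}

#' Write / read annotations as JSONL
#'
#' One annotation per line, for audit and reporting.
#'
#' @param annotations a single combined annotation data frame, or the named
#'   list from [annotate_record()].
#' @param path file path.
#' @return `read_annotations`: a combined annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  df <- combine_annotations(annotations)
  lines <- vapply(seq_len(nrow(df)), function(i) {
    as.character(jsonlite::toJSON(
      list(doc_id = df$doc_id[i], start = df$start[i], end = df$end[i],
           matched_text = df$matched_text[i], cui = df$cui[i],
           preferred_name = df$preferred_name[i],
           semantic_type = df$semantic_type[i], negated = df$negated[i],
           doc_timestamp = format_timestamp(df$doc_timestamp[i])),
      auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
  if (!length(rows)) return(tag_document_empty())
  df <- do.call(rbind, lapply(rows, function(x) {
    data.frame(doc_id = x$doc_id, start = as.integer(x$start),
               end = as.integer(x$end), matched_text = x$matched_text,
               cui = x$cui, preferred_name = x$preferred_name,
               semantic_type = x$semantic_type, negated = as.logical(x$negated),
               stringsAsFactors = FALSE)
  }))
  df$doc_timestamp <- parse_timestamp(vapply(rows, `[[`, character(1),
                                             "doc_timestamp"))
  df
}

tag_document_empty <- function() {
  empty <- data.frame(doc_id = character(0), start = integer(0),
                      end = integer(0), matched_text = character(0),
                      cui = character(0), preferred_name = character(0),
                      semantic_type = character(0), negated = logical(0),
                      stringsAsFactors = FALSE)
  empty$doc_timestamp <- as.POSIXct(numeric(0), origin = "1970-01-01",
                                    tz = "UTC")
  empty
}

#' Flatten an [annotate_record()] mapping into one data frame
#' @param annotations named list of annotation data frames, or one frame.
#' @return a single annotation data frame.
#' @export
combine_annotations <- function(annotations) {
  if (is.data.frame(annotations)) return(annotations)
  if (!length(annotations)) return(tag_document_empty())
  out <- do.call(rbind, annotations)
  rownames(out) <- NULL
  out
}
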