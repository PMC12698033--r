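#' @title Eligibility rule model
#' @description Typed constructors for eligibility-rule expressions (lab
#'   criteria, concept criteria, temporal windows, logical combinators),
#'   structural validation, a line-oriented authoring DSL, and a
#'   schema-versioned JSON rule-file format. Rule expressions are the
#'   machine-readable counterpart of checklist prose such as
#'   "Platelets <100,000" or "headache or head injury within three years".
#' @name rule_model
NULL

COMPARATORS <- c("LT", "LE", "GT", "GE", "EQ")
LAB_MODES <- c("ABSOLUTE", "RATIO_TO_CONTROL")
WINDOW_UNITS <- c("DAYS", "MONTHS", "YEARS")
WINDOW_DIRECTIONS <- c("BEFORE_INDEX", "AFTER_INDEX")
ROLES <- c("INCLUSION", "EXCLUSION")
RULE_SCHEMA_VERSION <- "1.0"

#' Temporal window
#'
#' A calendar window anchored at the patient's index time. Windows resolve to
#' half-open intervals (see [resolve_window()]): "within 7 days before index"
#' includes an event at exactly 7 days before the index time and excludes an
#' event at the index time itself.
#'
#' @param amount positive integer number of units.
#' @param unit `"DAYS"`, `"MONTHS"` or `"YEARS"`. Months and years use
#'   calendar arithmetic with month-end clamping, not fixed 30/365-day spans.
#' @param direction `"BEFORE_INDEX"` or `"AFTER_INDEX"`.
#' @return an object of class `temporal_window`.
#' @export
temporal_window <- function(amount, unit, direction = "BEFORE_INDEX") {
  amount <- as.integer(amount)
  if (length(amount) != 1L || is.na(amount) || amount < 1L)
    stop("window amount must be a positive integer", call. = FALSE)
  unit <- match.arg(unit, WINDOW_UNITS)
  direction <- match.arg(direction, WINDOW_DIRECTIONS)
  structure(list(amount = amount, unit = unit, direction = direction),
            class = "temporal_window")
}

#' Laboratory criterion
#'
#' Compares the most recent in-window result for a lab item against a
#' threshold. `ABSOLUTE` mode compares the raw value; `RATIO_TO_CONTROL`
#' compares `value / control_value`, as in "APTT <= 1.4 times the control
#' value".
#'
#' @param criterion_id identifier string, unique within an expression.
#' @param lab_item lab display name, or a `list(code=, name=)`.
#' @param comparator one of `"LT"`, `"LE"`, `"GT"`, `"GE"`, `"EQ"`.
#' @param threshold finite number; must be > 0 in ratio mode.
#' @param unit unit string, may be empty.
#' @param mode `"ABSOLUTE"` or `"RATIO_TO_CONTROL"`.
#' @param window optional [temporal_window()].
#' @return object of class `lab_criterion`.
#' @export
lab_criterion <- function(criterion_id, lab_item, comparator, threshold,
                          unit = "", mode = "ABSOLUTE", window = NULL) {
  if (is.character(lab_item)) lab_item <- list(code = lab_item, name = lab_item)
  stopifnot(is.list(lab_item), !is.null(lab_item$code), !is.null(lab_item$name))
  comparator <- match.arg(comparator, COMPARATORS)
  mode <- match.arg(mode, LAB_MODES)
  threshold <- as.numeric(threshold)
  if (length(threshold) != 1L || !is.finite(threshold))
    stop("threshold must be a finite number", call. = FALSE)
  if (mode == "RATIO_TO_CONTROL" && threshold <= 0)
    stop("ratio-to-control thresholds must be > 0", call. = FALSE)
  if (!is.null(window)) stopifnot(inherits(window, "temporal_window"))
  structure(list(criterion_id = as.character(criterion_id),
                 lab_item = list(code = as.character(lab_item$code),
                                 name = as.character(lab_item$name)),
                 comparator = comparator, threshold = threshold,
                 unit = as.character(unit), mode = mode, window = window),
            class = "lab_criterion")
}

#' Concept criterion
#'
#' Satisfied by a non-negated mention of any listed concept (a synonym family
#' for one clinical notion; conjunctions across notions are expressed with
#' `rule_and`) inside a document whose type is in `doc_types` and whose
#' timestamp falls in the window.
#'
#' @param criterion_id identifier string.
#' @param concepts data frame with columns `cui`, `preferred_name` (one row
#'   per concept), or a character vector of CUIs named by preferred name.
#' @param doc_types non-empty character vector of document-type labels.
#' @param window optional [temporal_window()].
#' @return object of class `concept_criterion`.
#' @export
concept_criterion <- function(criterion_id, concepts, doc_types, window = NULL) {
  if (is.character(concepts)) {
    nm <- names(concepts)
    if (is.null(nm)) nm <- concepts
    concepts <- data.frame(cui = unname(concepts), preferred_name = unname(nm),
                           stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(concepts),
            all(c("cui", "preferred_name") %in% names(concepts)))
  concepts <- data.frame(cui = as.character(concepts$cui),
                         preferred_name = as.character(concepts$preferred_name),
                         stringsAsFactors = FALSE)
  if (nrow(concepts) < 1L) stop("concepts list must be non-empty", call. = FALSE)
  if (anyDuplicated(concepts$cui))
    stop("concept CUIs must be unique within a criterion", call. = FALSE)
  doc_types <- as.character(doc_types)
  if (length(doc_types) < 1L) stop("doc_types must be non-empty", call. = FALSE)
  if (!is.null(window)) stopifnot(inherits(window, "temporal_window"))
  structure(list(criterion_id = as.character(criterion_id),
                 concepts = concepts, doc_types = doc_types, window = window),
            class = "concept_criterion")
}

#' Rule expression nodes
#'
#' A rule expression is a finite tree whose leaves are lab or concept
#' criteria and whose internal nodes are `AND` / `OR` (>= 2 children) or
#' `NOT` (exactly 1 child). Criterion objects are auto-wrapped into leaves.
#'
#' @param ... child expressions (or criteria) for `rule_and` / `rule_or`.
#' @param x the single child for `rule_not`, or the criterion for `rule_leaf`.
#' @return object of class `rule_expr`.
#' @export
rule_leaf <- function(x) {
  if (inherits(x, "rule_expr")) return(x)
  if (inherits(x, "lab_criterion"))
    return(structure(list(kind = "LAB", payload = x, children = NULL),
                     class = "rule_expr"))
  if (inherits(x, "concept_criterion"))
    return(structure(list(kind = "CONCEPT", payload = x, children = NULL),
                     class = "rule_expr"))
  stop("cannot make a rule leaf from class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

#' @rdname rule_leaf
#' @export
rule_and <- function(...) {
  children <- lapply(list(...), rule_leaf)
  if (length(children) < 2L) stop("AND requires >= 2 children", call. = FALSE)
  structure(list(kind = "AND", payload = NULL, children = children),
            class = "rule_expr")
}

#' @rdname rule_leaf
#' @export
rule_or <- function(...) {
  children <- lapply(list(...), rule_leaf)
  if (length(children) < 2L) stop("OR requires >= 2 children", call. = FALSE)
  structure(list(kind = "OR", payload = NULL, children = children),
            class = "rule_expr")
}

#' @rdname rule_leaf
#' @export
rule_not <- function(x) {
  structure(list(kind = "NOT", payload = NULL, children = list(rule_leaf(x))),
            class = "rule_expr")
}

#' Checklist of eligibility criteria
#'
#' @param trial_name trial name.
#' @param version version string.
#' @param items list of [checklist_item()]s. Labels must be unique; a
#'   checklist intended for screening should have at least one item (flagged
#'   by [validate_checklist()]), but an empty checklist is representable and
#'   screens to an empty verdict list.
#' @return object of class `eligibility_checklist`.
#' @export
checklist <- function(trial_name, version = "1", items = list()) {
  stopifnot(is.list(items))
  labels <- vapply(items, function(it) it$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate item label: ", labels[duplicated(labels)][1], call. = FALSE)
  structure(list(trial_name = as.character(trial_name),
                 version = as.character(version), items = items),
            class = "eligibility_checklist")
}

#' @rdname checklist
#' @param label verbatim criterion prose, unique within the checklist.
#' @param role `"INCLUSION"` or `"EXCLUSION"`.
#' @param expr the rule expression (criterion objects auto-wrapped).
#' @export
checklist_item <- function(label, role, expr) {
  role <- match.arg(role, ROLES)
  list(label = as.character(label), role = role, expr = rule_leaf(expr))
}

# ---------------------------------------------------------------------------
# Validation: violations are data, not exceptions, so that post-construction
# mutations are reportable.

violation <- function(path, message) {
  data.frame(path = path, message = message, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(path = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

validate_window <- function(w, path) {
  v <- no_violations()
  if (is.null(w)) return(v)
  if (!is.numeric(w$amount) && !is.integer(w$amount) ||
      length(w$amount) != 1L || is.na(w$amount) || w$amount < 1)
    v <- rbind(v, violation(path, "window amount must be >= 1"))
  if (!identical(length(w$unit), 1L) || !(w$unit %in% WINDOW_UNITS))
    v <- rbind(v, violation(path, "window unit not in {DAYS, MONTHS, YEARS}"))
  if (!identical(length(w$direction), 1L) ||
      !(w$direction %in% WINDOW_DIRECTIONS))
    v <- rbind(v, violation(path, "window direction invalid"))
  v
}

validate_lab_criterion <- function(p, path) {
  v <- no_violations()
  if (!is.numeric(p$threshold) || length(p$threshold) != 1L ||
      !is.finite(p$threshold))
    v <- rbind(v, violation(path, "threshold must be finite"))
  if (!(p$comparator %in% COMPARATORS))
    v <- rbind(v, violation(path, "comparator not in {LT, LE, GT, GE, EQ}"))
  if (!(p$mode %in% LAB_MODES))
    v <- rbind(v, violation(path, "mode not in {ABSOLUTE, RATIO_TO_CONTROL}"))
  if (identical(p$mode, "RATIO_TO_CONTROL") && is.numeric(p$threshold) &&
      length(p$threshold) == 1L && !is.na(p$threshold) && p$threshold <= 0)
    v <- rbind(v, violation(path, "RATIO_TO_CONTROL threshold must be > 0"))
  rbind(v, validate_window(p$window, paste0(path, ".window")))
}

validate_concept_criterion <- function(p, path) {
  v <- no_violations()
  if (!is.data.frame(p$concepts) || nrow(p$concepts) < 1L)
    v <- rbind(v, violation(path, "concepts list must have >= 1 entry"))
  else if (anyDuplicated(p$concepts$cui))
    v <- rbind(v, violation(path, "concept CUIs must be unique"))
  if (length(p$doc_types) < 1L)
    v <- rbind(v, violation(path, "doc_types must be non-empty"))
  rbind(v, validate_window(p$window, paste0(path, ".window")))
}

#' Validate a rule expression
#'
#' Checks every structural invariant of the expression tree: node kinds,
#' combinator arity (`AND`/`OR` need >= 2 children, `NOT` exactly 1, leaves
#' none), comparator/mode/unit enumerations, threshold finiteness and
#' ratio positivity, and window sanity. An empty report means the tree is
#' exactly what the typed constructors can build.
#'
#' @param expr a `rule_expr`.
#' @param path node path prefix used in violation messages.
#' @return data frame with columns `path`, `message`; zero rows when valid.
#' @export
validate_expr <- function(expr, path = "expr") {
  v <- no_violations()
  if (!is.list(expr) || is.null(expr$kind) ||
      !(expr$kind %in% c("LAB", "CONCEPT", "AND", "OR", "NOT")))
    return(rbind(v, violation(path, "unknown node kind")))
  if (expr$kind %in% c("LAB", "CONCEPT")) {
    if (!is.null(expr$children) && length(expr$children) > 0L)
      v <- rbind(v, violation(path, "leaves must have no children"))
    if (expr$kind == "LAB") {
      if (!inherits(expr$payload, "lab_criterion"))
        v <- rbind(v, violation(path, "LAB leaf payload must be a lab_criterion"))
      else v <- rbind(v, validate_lab_criterion(expr$payload, path))
    } else {
      if (!inherits(expr$payload, "concept_criterion"))
        v <- rbind(v, violation(path, "CONCEPT leaf payload must be a concept_criterion"))
      else v <- rbind(v, validate_concept_criterion(expr$payload, path))
    }
    return(v)
  }
  n <- length(expr$children)
  if (expr$kind %in% c("AND", "OR") && n < 2L)
    v <- rbind(v, violation(path, paste0(expr$kind, " requires >= 2 children")))
  if (expr$kind == "NOT" && n != 1L)
    v <- rbind(v, violation(path, "NOT requires exactly 1 child"))
  for (i in seq_len(n)) {
    v <- rbind(v, validate_expr(expr$children[[i]],
                                paste0(path, ".children[", i, "]")))
  }
  v
}

#' Validate a checklist
#'
#' @param cl an `eligibility_checklist`.
#' @return violation data frame as in [validate_expr()].
#' @export
validate_checklist <- function(cl) {
  v <- no_violations()
  if (length(cl$items) < 1L)
    v <- rbind(v, violation("items", "checklist must have >= 1 item"))
  labels <- vapply(cl$items, function(it) it$label, character(1))
  if (anyDuplicated(labels))
    v <- rbind(v, violation("items", paste0("duplicate item label: ",
                                            labels[duplicated(labels)][1])))
  for (i in seq_along(cl$items)) {
    it <- cl$items[[i]]
    if (!(it$role %in% ROLES))
      v <- rbind(v, violation(paste0("items[", i, "]"), "role invalid"))
    v <- rbind(v, validate_expr(it$expr, paste0("items[", i, "].expr")))
  }
  v
}

# ---------------------------------------------------------------------------
# JSON rule-file serialization (schema-versioned; unknown fields rejected).

window_to_list <- function(w) {
  if (is.null(w)) NULL
  else list(amount = w$amount, unit = w$unit, direction = w$direction)
}

expr_to_list <- function(e) {
  if (e$kind == "LAB") {
    p <- e$payload
    out <- list(kind = "LAB", criterion_id = p$criterion_id,
                lab_code = p$lab_item$code, lab_name = p$lab_item$name,
                comparator = p$comparator, threshold = p$threshold,
                unit = p$unit, mode = p$mode)
    if (!is.null(p$window)) out$window <- window_to_list(p$window)
    out
  } else if (e$kind == "CONCEPT") {
    p <- e$payload
    out <- list(kind = "CONCEPT", criterion_id = p$criterion_id,
                concepts = lapply(seq_len(nrow(p$concepts)), function(i) {
                  list(cui = p$concepts$cui[i],
                       preferred_name = p$concepts$preferred_name[i])
                }),
                doc_types = as.list(p$doc_types))
    if (!is.null(p$window)) out$window <- window_to_list(p$window)
    out
  } else {
    list(kind = e$kind, children = lapply(e$children, expr_to_list))
  }
}

check_fields <- function(x, required, optional = character(0), where) {
  nm <- names(x)
  missing <- setdiff(required, nm)
  if (length(missing))
    stop("malformed rule file: missing field(s) ",
         paste(missing, collapse = ", "), " in ", where, call. = FALSE)
  unknown <- setdiff(nm, c(required, optional))
  if (length(unknown))
    stop("malformed rule file: unknown field(s) ",
         paste(unknown, collapse = ", "), " in ", where, call. = FALSE)
  invisible(TRUE)
}

window_from_list <- function(x, where) {
  if (is.null(x)) return(NULL)
  check_fields(x, c("amount", "unit", "direction"), where = where)
  temporal_window(x$amount, x$unit, x$direction)
}

expr_from_list <- function(x, where = "expr") {
  if (is.null(x$kind)) stop("malformed rule file: node without kind in ",
                            where, call. = FALSE)
  kind <- x$kind
  if (kind == "LAB") {
    check_fields(x, c("kind", "criterion_id", "lab_code", "lab_name",
                      "comparator", "threshold", "unit", "mode"),
                 optional = "window", where = where)
    rule_leaf(lab_criterion(
      x$criterion_id, list(code = x$lab_code, name = x$lab_name),
      x$comparator, x$threshold, unit = x$unit, mode = x$mode,
      window = window_from_list(x$window, paste0(where, ".window"))))
  } else if (kind == "CONCEPT") {
    check_fields(x, c("kind", "criterion_id", "concepts", "doc_types"),
                 optional = "window", where = where)
    concepts <- data.frame(
      cui = vapply(x$concepts, function(c_) {
        check_fields(c_, c("cui", "preferred_name"), where = paste0(where, ".concepts"))
        as.character(c_$cui)
      }, character(1)),
      preferred_name = vapply(x$concepts, function(c_)
        as.character(c_$preferred_name), character(1)),
      stringsAsFactors = FALSE)
    rule_leaf(concept_criterion(
      x$criterion_id, concepts,
      vapply(x$doc_types, as.character, character(1)),
      window = window_from_list(x$window, paste0(where, ".window"))))
  } else if (kind %in% c("AND", "OR", "NOT")) {
    check_fields(x, c("kind", "children"), where = where)
    children <- lapply(seq_along(x$children), function(i)
      expr_from_list(x$children[[i]], paste0(where, ".children[", i, "]")))
    if (kind == "NOT") {
      if (length(children) != 1L)
        stop("malformed rule file: NOT with ", length(children),
             " children in ", where, call. = FALSE)
      rule_not(children[[1]])
    } else if (kind == "AND") do.call(rule_and, children)
    else do.call(rule_or, children)
  } else {
    stop("malformed rule file: unknown node kind '", kind, "' in ", where,
         call. = FALSE)
  }
}

#' Serialize / deserialize checklists to the rule-file format
#'
#' Rule files are JSON with a declared `schema_version`; unknown schema
#' versions and unknown fields are rejected rather than ignored (rule bases
#' are safety artifacts). `deserialize_checklist(serialize_checklist(x))` is
#' the identity on the structure.
#'
#' @param cl an `eligibility_checklist`.
#' @return `serialize_checklist`: a JSON string; `deserialize_checklist`: an
#'   `eligibility_checklist`.
#' @export
serialize_checklist <- function(cl) {
  stopifnot(inherits(cl, "eligibility_checklist"))
  doc <- list(schema_version = RULE_SCHEMA_VERSION,
              trial_name = cl$trial_name, version = cl$version,
              items = lapply(cl$items, function(it) {
                list(label = it$label, role = it$role,
                     expr = expr_to_list(it$expr))
              }))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"))
}

#' @rdname serialize_checklist
#' @param json JSON string or path handling is left to [read_checklist()].
#' @export
deserialize_checklist <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  check_fields(x, c("schema_version", "trial_name", "version", "items"),
               where = "checklist")
  if (!identical(x$schema_version, RULE_SCHEMA_VERSION))
    stop("unknown rule-file schema version: ", x$schema_version, call. = FALSE)
  items <- lapply(seq_along(x$items), function(i) {
    it <- x$items[[i]]
    check_fields(it, c("label", "role", "expr"),
                 where = paste0("items[", i, "]"))
    checklist_item(it$label, it$role,
                   expr_from_list(it$expr, paste0("items[", i, "].expr")))
  })
  checklist(x$trial_name, x$version, items)
}

#' @rdname serialize_checklist
#' @param path file path.
#' @export
write_checklist <- function(cl, path) {
  writeLines(serialize_checklist(cl), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname serialize_checklist
#' @export
read_checklist <- function(path) {
  deserialize_checklist(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
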