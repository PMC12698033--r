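#' @title Rule authoring DSL
#' @description A line-oriented text DSL for authoring eligibility checklists,
#'   the text counterpart of a drag-and-drop rule editor. One statement per
#'   checklist item; `#` starts a comment. Example:
#'
#' ```
#' trial "NINDS rt-PA"
#' version "1"
#' exclusion "Platelet count below 100,000": lab "Platelets" < 100000
#' exclusion "APTT above 1.4 times control":
#'     lab "APTT" > 1.4 x control within 7 days before index
#' exclusion "Headache or head injury within 3 years":
#'     (concept "Headache" in [outpatient note] within 3 years before index)
#'     or (concept "Head injury" in [outpatient note] within 3 years before index)
#' ```
#' @name dsl
NULL

# --- tokenizer --------------------------------------------------------------

dsl_tokenize <- function(lines, line_numbers) {
  toks <- list()
  push <- function(type, value, line, col) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value,
                                       line = line, col = col)
  }
  for (k in seq_along(lines)) {
    s <- lines[[k]]
    ln <- line_numbers[[k]]
    i <- 1L
    n <- nchar(s)
    while (i <= n) {
      ch <- substr(s, i, i)
      if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
      if (ch == "#") break
      if (ch == '"') {
        j <- i + 1L
        buf <- character(0)
        closed <- FALSE
        while (j <= n) {
          cj <- substr(s, j, j)
          if (cj == "\\" && j < n) {
            buf <- c(buf, substr(s, j + 1L, j + 1L)); j <- j + 2L
          } else if (cj == '"') { closed <- TRUE; break }
          else { buf <- c(buf, cj); j <- j + 1L }
        }
        if (!closed)
          stop(sprintf("DSL syntax error at line %d, col %d: unterminated string",
                       ln, i), call. = FALSE)
        push("STR", paste(buf, collapse = ""), ln, i)
        i <- j + 1L
        next
      }
      if (grepl("^[0-9]", ch) ||
          (ch %in% c(".", "-") && i < n &&
             grepl("^[0-9.]", substr(s, i + 1L, i + 1L)))) {
        m <- regmatches(substr(s, i, n),
                        regexpr("^-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?",
                                substr(s, i, n)))
        push("NUM", as.numeric(m), ln, i)
        i <- i + nchar(m)
        next
      }
      if (ch %in% c("(", ")", "[", "]", ",", ":")) {
        push("PUNCT", ch, ln, i); i <- i + 1L; next
      }
      if (ch %in% c("<", ">", "=", "!")) {
        two <- substr(s, i, min(i + 1L, n))
        if (two %in% c("<=", ">=", "==")) {
          push("OP", sub("==", "=", two), ln, i); i <- i + 2L
        } else {
          push("OP", ch, ln, i); i <- i + 1L
        }
        next
      }
      if (grepl("^[A-Za-z_]", ch)) {
        m <- regmatches(substr(s, i, n),
                        regexpr("^[A-Za-z_][A-Za-z0-9_-]*", substr(s, i, n)))
        push("WORD", m, ln, i)
        i <- i + nchar(m)
        next
      }
      stop(sprintf("DSL syntax error at line %d, col %d: unexpected character '%s'",
                   ln, i, ch), call. = FALSE)
    }
  }
  toks
}

# --- token-stream cursor ----------------------------------------------------

new_cursor <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$pos <- 1L
  env
}

cur_peek <- function(cu, ahead = 0L) {
  p <- cu$pos + ahead
  if (p > length(cu$tokens)) NULL else cu$tokens[[p]]
}

cur_next <- function(cu) {
  t <- cur_peek(cu)
  cu$pos <- cu$pos + 1L
  t
}

cur_where <- function(cu) {
  t <- cur_peek(cu)
  if (is.null(t)) {
    last <- cu$tokens[[length(cu$tokens)]]
    sprintf("line %d, col %d (end of statement)", last$line,
            last$col + nchar(as.character(last$value)))
  } else sprintf("line %d, col %d", t$line, t$col)
}

cur_expect <- function(cu, type, value = NULL) {
  t <- cur_peek(cu)
  ok <- !is.null(t) && t$type == type &&
    (is.null(value) || identical(tolower(as.character(t$value)), tolower(value)))
  if (!ok)
    stop(sprintf("DSL syntax error at %s: expected %s", cur_where(cu),
                 if (is.null(value)) type else paste0("'", value, "'")),
         call. = FALSE)
  cur_next(cu)
}

cur_is_word <- function(cu, word, ahead = 0L) {
  t <- cur_peek(cu, ahead)
  !is.null(t) && t$type == "WORD" && tolower(t$value) == word
}

# --- expression parser ------------------------------------------------------

parse_window <- function(cu) {
  if (!cur_is_word(cu, "within")) return(NULL)
  cur_next(cu)
  t <- cur_peek(cu)
  if (is.null(t) || t$type != "NUM")
    stop(sprintf("DSL syntax error at %s: expected a number after 'within'",
                 cur_where(cu)), call. = FALSE)
  amount <- cur_next(cu)$value
  ut <- cur_peek(cu)
  if (is.null(ut) || ut$type != "WORD")
    stop(sprintf("DSL syntax error at %s: expected a time unit", cur_where(cu)),
         call. = FALSE)
  unit <- switch(tolower(cur_next(cu)$value),
                 day = , days = "DAYS",
                 month = , months = "MONTHS",
                 year = , years = "YEARS",
                 stop(sprintf("DSL syntax error at line %d, col %d: unknown time unit '%s'",
                              ut$line, ut$col, ut$value), call. = FALSE))
  dt <- cur_peek(cu)
  direction <- if (cur_is_word(cu, "before")) { cur_next(cu); "BEFORE_INDEX" }
  else if (cur_is_word(cu, "after")) { cur_next(cu); "AFTER_INDEX" }
  else stop(sprintf("DSL syntax error at %s: expected 'before' or 'after'",
                    cur_where(cu)), call. = FALSE)
  cur_expect(cu, "WORD", "index")
  temporal_window(amount, unit, direction)
}

parse_doc_type_item <- function(cu) {
  t <- cur_peek(cu)
  if (!is.null(t) && t$type == "STR") return(cur_next(cu)$value)
  words <- character(0)
  repeat {
    t <- cur_peek(cu)
    if (is.null(t) || t$type != "WORD") break
    words <- c(words, cur_next(cu)$value)
  }
  if (!length(words))
    stop(sprintf("DSL syntax error at %s: expected a document type label",
                 cur_where(cu)), call. = FALSE)
  paste(words, collapse = " ")
}

#' Derive a local concept identifier from a display name
#'
#' Used when parsing DSL without a lexicon: concept references get
#' deterministic `local:` CUIs derived from the name.
#' @param name concept display name.
#' @return character CUI.
#' @export
local_cui <- function(name) {
  paste0("local:", gsub("(^_)|(_$)", "", gsub("[^a-z0-9]+", "_", tolower(name))))
}

resolve_concept <- function(name, lexicon, tok) {
  if (is.null(lexicon))
    return(c(cui = local_cui(name), preferred_name = name))
  hit <- lexicon_lookup_name(lexicon, name)
  if (is.null(hit))
    stop(sprintf("resolution error at line %d, col %d: concept '%s' is not in the lexicon",
                 tok$line, tok$col, name), call. = FALSE)
  c(cui = hit$cui, preferred_name = hit$preferred_name)
}

parse_primary <- function(cu, ctx) {
  t <- cur_peek(cu)
  if (is.null(t))
    stop(sprintf("DSL syntax error at %s: unexpected end of statement",
                 cur_where(cu)), call. = FALSE)
  if (t$type == "PUNCT" && t$value == "(") {
    cur_next(cu)
    e <- parse_or(cu, ctx)
    cur_expect(cu, "PUNCT", ")")
    return(e)
  }
  if (cur_is_word(cu, "not")) {
    cur_next(cu)
    return(rule_not(parse_primary(cu, ctx)))
  }
  if (cur_is_word(cu, "lab")) {
    cur_next(cu)
    nt <- cur_peek(cu)
    if (is.null(nt) || nt$type != "STR")
      stop(sprintf("DSL syntax error at %s: expected a quoted lab name",
                   cur_where(cu)), call. = FALSE)
    name <- cur_next(cu)$value
    if (!is.null(ctx$lab_items) && !(name %in% ctx$lab_items))
      stop(sprintf("resolution error at line %d, col %d: lab item '%s' is not declared",
                   nt$line, nt$col, name), call. = FALSE)
    ot <- cur_peek(cu)
    if (is.null(ot) || ot$type != "OP")
      stop(sprintf("DSL syntax error at %s: expected a comparator",
                   cur_where(cu)), call. = FALSE)
    comparator <- switch(cur_next(cu)$value,
                         "<" = "LT", "<=" = "LE", ">" = "GT", ">=" = "GE",
                         "=" = "EQ",
                         stop(sprintf("DSL syntax error at line %d, col %d: unknown comparator",
                                      ot$line, ot$col), call. = FALSE))
    vt <- cur_peek(cu)
    if (is.null(vt) || vt$type != "NUM")
      stop(sprintf("DSL syntax error at %s: expected a numeric threshold",
                   cur_where(cu)), call. = FALSE)
    threshold <- cur_next(cu)$value
    mode <- "ABSOLUTE"
    if (cur_is_word(cu, "x") || cur_is_word(cu, "times")) {
      cur_next(cu)
      cur_expect(cu, "WORD", "control")
      mode <- "RATIO_TO_CONTROL"
    }
    unit <- ""
    if (cur_is_word(cu, "unit")) {
      cur_next(cu)
      st <- cur_peek(cu)
      if (is.null(st) || st$type != "STR")
        stop(sprintf("DSL syntax error at %s: expected a quoted unit",
                     cur_where(cu)), call. = FALSE)
      unit <- cur_next(cu)$value
    }
    window <- parse_window(cu)
    ctx$leaf <- ctx$leaf + 1L
    return(rule_leaf(lab_criterion(
      sprintf("c%d_%d", ctx$item, ctx$leaf), name, comparator, threshold,
      unit = unit, mode = mode, window = window)))
  }
  if (cur_is_word(cu, "concept")) {
    cur_next(cu)
    names_ <- character(0)
    toks <- list()
    nt <- cur_peek(cu)
    if (!is.null(nt) && nt$type == "PUNCT" && nt$value == "[") {
      cur_next(cu)
      repeat {
        st <- cur_peek(cu)
        if (is.null(st) || st$type != "STR")
          stop(sprintf("DSL syntax error at %s: expected a quoted concept name",
                       cur_where(cu)), call. = FALSE)
        names_ <- c(names_, st$value)
        toks[[length(toks) + 1L]] <- st
        cur_next(cu)
        ct <- cur_peek(cu)
        if (!is.null(ct) && ct$type == "PUNCT" && ct$value == ",") {
          cur_next(cu); next
        }
        cur_expect(cu, "PUNCT", "]")
        break
      }
    } else if (!is.null(nt) && nt$type == "STR") {
      names_ <- cur_next(cu)$value
      toks[[1L]] <- nt
    } else {
      stop(sprintf("DSL syntax error at %s: expected a quoted concept name",
                   cur_where(cu)), call. = FALSE)
    }
    resolved <- lapply(seq_along(names_), function(i)
      resolve_concept(names_[i], ctx$lexicon, toks[[i]]))
    concepts <- data.frame(
      cui = vapply(resolved, `[[`, character(1), "cui"),
      preferred_name = vapply(resolved, `[[`, character(1), "preferred_name"),
      stringsAsFactors = FALSE)
    cur_expect(cu, "WORD", "in")
    cur_expect(cu, "PUNCT", "[")
    doc_types <- character(0)
    repeat {
      doc_types <- c(doc_types, parse_doc_type_item(cu))
      ct <- cur_peek(cu)
      if (!is.null(ct) && ct$type == "PUNCT" && ct$value == ",") {
        cur_next(cu); next
      }
      cur_expect(cu, "PUNCT", "]")
      break
    }
    window <- parse_window(cu)
    ctx$leaf <- ctx$leaf + 1L
    return(rule_leaf(concept_criterion(
      sprintf("c%d_%d", ctx$item, ctx$leaf), concepts, doc_types,
      window = window)))
  }
  stop(sprintf("DSL syntax error at line %d, col %d: expected 'lab', 'concept', 'not' or '('",
               t$line, t$col), call. = FALSE)
}

parse_and <- function(cu, ctx) {
  children <- list(parse_primary(cu, ctx))
  while (cur_is_word(cu, "and")) {
    cur_next(cu)
    children[[length(children) + 1L]] <- parse_primary(cu, ctx)
  }
  if (length(children) == 1L) children[[1L]] else do.call(rule_and, children)
}

parse_or <- function(cu, ctx) {
  children <- list(parse_and(cu, ctx))
  while (cur_is_word(cu, "or")) {
    cur_next(cu)
    children[[length(children) + 1L]] <- parse_and(cu, ctx)
  }
  if (length(children) == 1L) children[[1L]] else do.call(rule_or, children)
}

# --- statement-level parser -------------------------------------------------

#' Parse rule-DSL source into a checklist
#'
#' A statement begins with `inclusion` or `exclusion`, a quoted criterion
#' label, a colon, and a rule expression; statements may continue over
#' following lines. Optional `trial "..."` and `version "..."` header lines
#' name the checklist. Errors report the offending line and column. When a
#' `lexicon` is supplied, concept names must resolve against it (preferred
#' name or any surface form); otherwise concepts get deterministic `local:`
#' identifiers. When `lab_items` is supplied, lab names outside it are
#' resolution errors.
#'
#' @param text DSL source (single string or character vector of lines).
#' @param lexicon optional [lexicon()] for concept resolution.
#' @param lab_items optional character vector of declared lab item names.
#' @return an `eligibility_checklist`.
#' @export
parse_dsl <- function(text, lexicon = NULL, lab_items = NULL) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  if (!length(lines)) lines <- ""
  all_toks <- dsl_tokenize(lines, seq_along(lines))
  trial_name <- ""
  version <- "1"
  items <- list()
  # split the token stream into statements
  i <- 1L
  n <- length(all_toks)
  starts_stmt <- function(t) t$type == "WORD" &&
    tolower(t$value) %in% c("trial", "version", "inclusion", "exclusion")
  item_no <- 0L
  while (i <= n) {
    t <- all_toks[[i]]
    if (!starts_stmt(t))
      stop(sprintf("DSL syntax error at line %d, col %d: expected 'trial', 'version', 'inclusion' or 'exclusion'",
                   t$line, t$col), call. = FALSE)
    kw <- tolower(t$value)
    j <- i + 1L
    while (j <= n && !starts_stmt(all_toks[[j]])) j <- j + 1L
    stmt <- all_toks[seq.int(i, j - 1L)]
    cu <- new_cursor(stmt)
    cur_next(cu)  # keyword
    if (kw %in% c("trial", "version")) {
      st <- cur_peek(cu)
      if (is.null(st) || st$type != "STR")
        stop(sprintf("DSL syntax error at %s: expected a quoted string after '%s'",
                     cur_where(cu), kw), call. = FALSE)
      val <- cur_next(cu)$value
      if (!is.null(cur_peek(cu)))
        stop(sprintf("DSL syntax error at %s: trailing tokens after %s header",
                     cur_where(cu), kw), call. = FALSE)
      if (kw == "trial") trial_name <- val else version <- val
    } else {
      item_no <- item_no + 1L
      lt <- cur_peek(cu)
      if (is.null(lt) || lt$type != "STR")
        stop(sprintf("DSL syntax error at %s: expected a quoted criterion label",
                     cur_where(cu)), call. = FALSE)
      label <- cur_next(cu)$value
      cur_expect(cu, "PUNCT", ":")
      ctx <- new.env(parent = emptyenv())
      ctx$item <- item_no
      ctx$leaf <- 0L
      ctx$lexicon <- lexicon
      ctx$lab_items <- lab_items
      expr <- parse_or(cu, ctx)
      left <- cur_peek(cu)
      if (!is.null(left))
        stop(sprintf("DSL syntax error at line %d, col %d: trailing tokens after expression",
                     left$line, left$col), call. = FALSE)
      items[[length(items) + 1L]] <-
        checklist_item(label, toupper(kw), expr)
    }
    i <- j
  }
  if (!length(items)) stop("DSL contains no checklist items", call. = FALSE)
  checklist(trial_name, version, items)
}

# --- pretty printer ---------------------------------------------------------

fmt_num <- function(x) {
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g", width = 1)
    if (as.numeric(s) == x) return(s)
  }
  sprintf("%.17g", x)
}

dsl_quote <- function(s) {
  paste0('"', gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", s)), '"')
}

fmt_window <- function(w) {
  if (is.null(w)) return("")
  sprintf(" within %d %s %s index", w$amount, tolower(w$unit),
          if (w$direction == "BEFORE_INDEX") "before" else "after")
}

fmt_leaf <- function(e) {
  p <- e$payload
  if (e$kind == "LAB") {
    op <- c(LT = "<", LE = "<=", GT = ">", GE = ">=", EQ = "=")[p$comparator]
    paste0("lab ", dsl_quote(p$lab_item$name), " ", op, " ",
           fmt_num(p$threshold),
           if (p$mode == "RATIO_TO_CONTROL") " x control" else "",
           if (nzchar(p$unit)) paste0(" unit ", dsl_quote(p$unit)) else "",
           fmt_window(p$window))
  } else {
    nm <- p$concepts$preferred_name
    cpart <- if (length(nm) == 1L) dsl_quote(nm)
    else paste0("[", paste(vapply(nm, dsl_quote, character(1)),
                           collapse = ", "), "]")
    paste0("concept ", cpart, " in [", paste(p$doc_types, collapse = ", "),
           "]", fmt_window(p$window))
  }
}

fmt_expr <- function(e) {
  switch(e$kind,
         LAB = , CONCEPT = fmt_leaf(e),
         NOT = paste0("not (", fmt_expr(e$children[[1]]), ")"),
         AND = paste(vapply(e$children, function(c_)
           paste0("(", fmt_expr(c_), ")"), character(1)), collapse = " and "),
         OR = paste(vapply(e$children, function(c_)
           paste0("(", fmt_expr(c_), ")"), character(1)), collapse = " or "))
}

#' Pretty-print a checklist as DSL source
#'
#' Emits canonical DSL that [parse_dsl()] parses back to a structurally
#' identical checklist (`parse_dsl(pretty_print(x))` is the identity, given
#' the same lexicon context).
#'
#' @param cl an `eligibility_checklist`.
#' @return single string of DSL source.
#' @export
pretty_print <- function(cl) {
  stopifnot(inherits(cl, "eligibility_checklist"))
  out <- c(paste0("trial ", dsl_quote(cl$trial_name)),
           paste0("version ", dsl_quote(cl$version)))
  for (it in cl$items) {
    out <- c(out, paste0(tolower(it$role), " ", dsl_quote(it$label), ": ",
                         fmt_expr(it$expr)))
  }
  paste(out, collapse = "\n")
}
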