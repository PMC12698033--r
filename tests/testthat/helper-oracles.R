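# Independent oracles and random-case generators shared by the suite.
# The oracles are written directly from the criterion definitions and from
# explicit three-valued truth tables; they share no evaluation code with the
# inference engine.

.ST <- c("MET", "NOT_MET", "UNKNOWN")

# explicit strong-Kleene truth tables (binary)
.and2 <- matrix(c("MET",     "NOT_MET", "UNKNOWN",
                  "NOT_MET", "NOT_MET", "NOT_MET",
                  "UNKNOWN", "NOT_MET", "UNKNOWN"),
                nrow = 3, byrow = TRUE, dimnames = list(.ST, .ST))
.or2 <- matrix(c("MET", "MET",     "MET",
                 "MET", "NOT_MET", "UNKNOWN",
                 "MET", "UNKNOWN", "UNKNOWN"),
               nrow = 3, byrow = TRUE, dimnames = list(.ST, .ST))
.not1 <- c(MET = "NOT_MET", NOT_MET = "MET", UNKNOWN = "UNKNOWN")

oracle_and <- function(ss) Reduce(function(a, b) .and2[a, b], ss)
oracle_or <- function(ss) Reduce(function(a, b) .or2[a, b], ss)

# Brute-force criterion evaluation: enumerate every lab row / every
# (document, annotation) pair directly from the definitions.
oracle_lab_status <- function(crit, record) {
  iv <- if (is.null(crit$window)) NULL
  else resolve_window(crit$window, record$index_time)
  best <- NULL
  for (i in seq_len(nrow(record$labs))) {
    if (record$labs$item[i] != crit$lab_item$code) next
    ts <- record$labs$timestamp[i]
    if (!is.null(iv) && !(ts >= iv$start && ts < iv$end)) next
    if (is.null(best) || ts >= record$labs$timestamp[best]) best <- i
  }
  if (is.null(best)) return("UNKNOWN")
  val <- record$labs$value[best]
  if (crit$mode == "RATIO_TO_CONTROL") {
    ctrl <- record$labs$control_value[best]
    if (is.na(ctrl)) return("UNKNOWN")
    val <- val / ctrl
  }
  cmp <- switch(crit$comparator, LT = `<`, LE = `<=`, GT = `>`, GE = `>=`,
                EQ = `==`)
  if (cmp(val, crit$threshold)) "MET" else "NOT_MET"
}

oracle_concept_status <- function(crit, record, ann_by_doc) {
  any_type <- FALSE
  found <- FALSE
  iv <- if (is.null(crit$window)) NULL
  else resolve_window(crit$window, record$index_time)
  for (doc in record$documents) {
    if (!(doc$doc_type %in% crit$doc_types)) next
    any_type <- TRUE
    if (!is.null(iv) && !(doc$timestamp >= iv$start && doc$timestamp < iv$end))
      next
    ann <- ann_by_doc[[doc$doc_id]]
    if (is.null(ann) || !nrow(ann)) next
    for (j in seq_len(nrow(ann))) {
      if (!ann$negated[j] && ann$cui[j] %in% crit$concepts$cui) found <- TRUE
    }
  }
  if (!any_type) return("UNKNOWN")
  if (found) "MET" else "NOT_MET"
}

oracle_eval <- function(expr, record, ann_by_doc) {
  switch(expr$kind,
         LAB = oracle_lab_status(expr$payload, record),
         CONCEPT = oracle_concept_status(expr$payload, record, ann_by_doc),
         NOT = .not1[[oracle_eval(expr$children[[1]], record, ann_by_doc)]],
         AND = oracle_and(vapply(expr$children, oracle_eval, character(1),
                                 record = record, ann_by_doc = ann_by_doc)),
         OR = oracle_or(vapply(expr$children, oracle_eval, character(1),
                               record = record, ann_by_doc = ann_by_doc)))
}

# Brute-force P/R/F1: enumerate every (prediction, gold) pair per CUI.
oracle_prf <- function(pred, gold, policy = "overlap") {
  pred <- pred[!pred$negated, , drop = FALSE]
  gold <- gold[!gold$negated, , drop = FALSE]
  out <- list()
  for (cui in sort(unique(c(pred$cui, gold$cui)))) {
    p <- pred[pred$cui == cui, , drop = FALSE]
    g <- gold[gold$cui == cui, , drop = FALSE]
    match_pg <- function(i, j) {
      if (p$doc_id[i] != g$doc_id[j]) return(FALSE)
      if (policy == "exact") p$start[i] == g$start[j] && p$end[i] == g$end[j]
      else p$start[i] < g$end[j] && g$start[j] < p$end[i]
    }
    tp <- 0L
    fn <- 0L
    for (j in seq_len(nrow(g))) {
      hit <- any(vapply(seq_len(nrow(p)), function(i) match_pg(i, j),
                        logical(1)))
      if (hit) tp <- tp + 1L else fn <- fn + 1L
    }
    fp <- 0L
    for (i in seq_len(nrow(p))) {
      hit <- any(vapply(seq_len(nrow(g)), function(j) match_pg(i, j),
                        logical(1)))
      if (!hit) fp <- fp + 1L
    }
    out[[cui]] <- c(tp = tp, fp = fp, fn = fn)
  }
  out
}

# --- random-case generators -------------------------------------------------

.test_lab_items <- c("Platelets", "Glucose", "APTT", "INR")
.test_doc_types <- c("admission note", "outpatient note", "discharge summary",
                     "er note")

random_window <- function() {
  if (runif(1) < 0.4) return(NULL)
  temporal_window(sample(c(1:30, 90, 365), 1),
                  sample(c("DAYS", "MONTHS", "YEARS"), 1),
                  sample(c("BEFORE_INDEX", "AFTER_INDEX"), 1,
                         prob = c(0.9, 0.1)))
}

random_leaf <- function(id, lex) {
  if (runif(1) < 0.5) {
    mode <- if (runif(1) < 0.3) "RATIO_TO_CONTROL" else "ABSOLUTE"
    thr <- if (mode == "RATIO_TO_CONTROL") runif(1, 0.5, 2)
    else runif(1, -10, 300000)
    rule_leaf(lab_criterion(id, sample(.test_lab_items, 1),
                            sample(c("LT", "LE", "GT", "GE", "EQ"), 1),
                            thr, mode = mode, window = random_window()))
  } else {
    cuis <- sample(unique(lex$cui), sample(1:2, 1))
    nm <- lex$preferred_name[match(cuis, lex$cui)]
    rule_leaf(concept_criterion(
      id, data.frame(cui = cuis, preferred_name = nm,
                     stringsAsFactors = FALSE),
      sample(.test_doc_types, sample(1:3, 1)), window = random_window()))
  }
}

random_expr <- function(depth, lex, counter = new.env()) {
  if (is.null(counter$n)) counter$n <- 0L
  counter$n <- counter$n + 1L
  id <- sprintf("r%d", counter$n)
  if (depth <= 0 || runif(1) < 0.35) return(random_leaf(id, lex))
  kind <- sample(c("AND", "OR", "NOT"), 1)
  if (kind == "NOT") return(rule_not(random_expr(depth - 1, lex, counter)))
  k <- sample(2:3, 1)
  children <- lapply(seq_len(k), function(i)
    random_expr(depth - 1, lex, counter))
  if (kind == "AND") do.call(rule_and, children) else do.call(rule_or, children)
}

# A small random patient: <= 8 documents with planted mentions, <= 8 labs.
random_small_record <- function(lex) {
  index_time <- parse_timestamp("2024-06-15T10:30:00Z")
  n_docs <- sample(0:8, 1)
  docs <- lapply(seq_len(n_docs), function(i) {
    forms_n <- sample(0:3, 1)
    sentences <- "Review of systems completed."
    for (k in seq_len(forms_n)) {
      form <- sample(lex$surface_form, 1)
      neg <- runif(1) < 0.3
      sentences <- c(sentences,
                     if (neg) paste0("No ", form, " reported.")
                     else paste0("Documented ", form, " this visit."))
    }
    clinical_document(sprintf("d%02d", i), sample(.test_doc_types, 1),
                      index_time + sample(-800:5, 1) * 86400,
                      paste(sentences, collapse = " "))
  })
  n_labs <- sample(0:8, 1)
  labs <- lab_table(
    item = sample(.test_lab_items, n_labs, replace = TRUE),
    value = round(runif(n_labs, 0.5, 300000), 2),
    unit = rep("", n_labs),
    control_value = ifelse(runif(n_labs) < 0.4, round(runif(n_labs, 20, 40), 1),
                           NA_real_),
    timestamp = format_timestamp(index_time + sample(-800:5, n_labs,
                                                     replace = TRUE) * 86400))
  patient_record("pt-test", index_time, docs, labs)
}

# Random checklists for round-trip laws; criterion ids follow the DSL
# numbering scheme so pretty-print/parse identity is exact.
random_checklist <- function() {
  lex <- default_lexicon()
  n <- sample(1:5, 1)
  items <- lapply(seq_len(n), function(i) {
    leaf_no <- new.env(); leaf_no$k <- 0L
    mk <- function(depth) {
      if (depth <= 0 || runif(1) < 0.45) {
        leaf_no$k <- leaf_no$k + 1L
        id <- sprintf("c%d_%d", i, leaf_no$k)
        if (runif(1) < 0.5) {
          mode <- if (runif(1) < 0.3) "RATIO_TO_CONTROL" else "ABSOLUTE"
          thr <- if (mode == "RATIO_TO_CONTROL") round(runif(1, 0.5, 2), 3)
          else round(runif(1, -50, 500), 2)
          rule_leaf(lab_criterion(id, sample(.test_lab_items, 1),
                                  sample(c("LT", "LE", "GT", "GE", "EQ"), 1),
                                  thr, mode = mode,
                                  window = random_window()))
        } else {
          k <- sample(1:2, 1)
          nms <- sample(unique(lex$preferred_name), k)
          rule_leaf(concept_criterion(
            id, data.frame(cui = vapply(nms, local_cui, character(1),
                                        USE.NAMES = FALSE),
                           preferred_name = nms, stringsAsFactors = FALSE),
            sample(.test_doc_types, sample(1:3, 1)),
            window = random_window()))
        }
      } else {
        kind <- sample(c("AND", "OR", "NOT"), 1)
        if (kind == "NOT") rule_not(mk(depth - 1))
        else {
          ch <- lapply(seq_len(sample(2:3, 1)), function(j) mk(depth - 1))
          if (kind == "AND") do.call(rule_and, ch) else do.call(rule_or, ch)
        }
      }
    }
    checklist_item(sprintf("criterion %d", i),
                   sample(c("INCLUSION", "EXCLUSION"), 1), mk(3))
  })
  checklist(paste0("trial-", sample(1000:9999, 1)),
            as.character(sample(1:9, 1)), items)
}
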