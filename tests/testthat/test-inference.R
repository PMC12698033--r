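lab_rec <- function(items, values, controls, offsets_days,
                    idx = "2024-06-15T00:00:00Z") {
  n <- length(items)
  patient_record("p", idx, list(), lab_table(
    item = items, value = values, unit = rep("", n),
    control_value = controls,
    timestamp = format_timestamp(parse_timestamp(idx) +
                                   offsets_days * 86400)))
}

test_that("lab criteria compare the latest in-window value", {
  rec <- lab_rec("Platelets", 95000, NA, -1)
  v <- eval_lab_criterion(lab_criterion("c", "Platelets", "LT", 100000), rec)
  expect_identical(v$status, "MET")
  expect_length(v$evidence, 1)
  expect_identical(v$evidence[[1]]$type, "lab")
  expect_identical(v$evidence[[1]]$value, 95000)

  v2 <- eval_lab_criterion(lab_criterion("c", "Platelets", "LT", 90000), rec)
  expect_identical(v2$status, "NOT_MET")
})

test_that("ratio-to-control uses value/control and handles missing data", {
  rec <- lab_rec("APTT", 42, 30, -3)
  crit <- lab_criterion("c", "APTT", "LE", 1.4, mode = "RATIO_TO_CONTROL",
                        window = temporal_window(7, "DAYS"))
  expect_identical(eval_lab_criterion(crit, rec)$status, "MET")  # 42/30 = 1.4

  # no in-window result -> UNKNOWN
  rec_old <- lab_rec("APTT", 42, 30, -10)
  v <- eval_lab_criterion(crit, rec_old)
  expect_identical(v$status, "UNKNOWN")
  expect_length(v$evidence, 0)
  expect_match(v$explanation, "no in-window result")

  # missing control in ratio mode -> UNKNOWN with explanation
  rec_nc <- lab_rec("APTT", 42, NA, -3)
  v2 <- eval_lab_criterion(crit, rec_nc)
  expect_identical(v2$status, "UNKNOWN")
  expect_match(v2$explanation, "control value")
})

concept_fixture <- function(offset_years, doc_type = "outpatient note",
                            negated = FALSE) {
  idx <- parse_timestamp("2024-06-15T00:00:00Z")
  doc <- clinical_document("d1", doc_type,
                           idx - offset_years * 365 * 86400,
                           if (negated) "No history of head injury."
                           else "History of head injury documented.")
  rec <- patient_record("p", idx, list(doc))
  ann <- annotate_record(rec, default_lexicon(), NULL,
                         default_negation_rules())
  list(rec = rec, ann = ann)
}

hi_crit <- function() {
  concept_criterion("c", c(`Head injury` = "C0018674"),
                    c("outpatient note", "admission note"),
                    window = temporal_window(3, "YEARS"))
}

test_that("concept criteria demand affirmed, typed, in-window mentions", {
  fx <- concept_fixture(2)
  v <- eval_concept_criterion(hi_crit(), fx$rec, fx$ann)
  expect_identical(v$status, "MET")
  expect_length(v$evidence, 1)
  expect_identical(v$evidence[[1]]$doc_id, "d1")

  # only a negated mention -> NOT_MET with empty evidence
  fx_neg <- concept_fixture(2, negated = TRUE)
  v2 <- eval_concept_criterion(hi_crit(), fx_neg$rec, fx_neg$ann)
  expect_identical(v2$status, "NOT_MET")
  expect_length(v2$evidence, 0)

  # affirmed but out of window -> NOT_MET
  fx_old <- concept_fixture(4)
  expect_identical(eval_concept_criterion(hi_crit(), fx_old$rec,
                                          fx_old$ann)$status, "NOT_MET")

  # no documents of the requested types at all -> UNKNOWN
  fx_wrong <- concept_fixture(2, doc_type = "nursing note")
  v3 <- eval_concept_criterion(hi_crit(), fx_wrong$rec, fx_wrong$ann)
  expect_identical(v3$status, "UNKNOWN")
})

test_that("combinators follow the strong-Kleene tables", {
  expect_identical(kleene_and(c("MET", "MET")), "MET")
  expect_identical(kleene_and(c("MET", "UNKNOWN")), "UNKNOWN")
  expect_identical(kleene_and(c("NOT_MET", "UNKNOWN")), "NOT_MET")
  expect_identical(kleene_or(c("NOT_MET", "UNKNOWN")), "UNKNOWN")
  expect_identical(kleene_or(c("MET", "UNKNOWN")), "MET")
  expect_identical(kleene_not("NOT_MET"), "MET")
  expect_identical(kleene_not("UNKNOWN"), "UNKNOWN")
})

test_that("a diabetes-with-prior-stroke conjunction is MET across documents", {
  idx <- parse_timestamp("2024-06-15T00:00:00Z")
  docs <- list(
    clinical_document("d1", "outpatient note", idx - 400 * 86400,
                      "Known diabetes in the medical record."),
    clinical_document("d2", "discharge summary", idx - 700 * 86400,
                      "History of ischemic stroke documented."))
  rec <- patient_record("p", idx, docs)
  ann <- annotate_record(rec, default_lexicon(), NULL,
                         default_negation_rules())
  types <- c("outpatient note", "discharge summary")
  expr <- rule_and(
    concept_criterion("a", c(`Diabetes mellitus` = "C0011849"), types),
    concept_criterion("b", c(Stroke = "C0038454"), types))
  v <- eval_expr(expr, rec, ann)
  expect_identical(v$status, "MET")
  expect_setequal(vapply(v$evidence, function(e) e$doc_id, character(1)),
                  c("d1", "d2"))
})

test_that("eval_expr matches the brute-force oracle on random cases", {
  set.seed(2024)
  lex <- default_lexicon()
  rules <- default_negation_rules()
  for (rep in 1:40) {
    rec <- random_small_record(lex)
    ann <- annotate_record(rec, lex, NULL, rules)
    for (k in 1:5) {
      expr <- random_expr(4, lex)
      expect_identical(eval_expr(expr, rec, ann)$status,
                       oracle_eval(expr, rec, ann))
    }
  }
})

test_that("screening yields one ordered verdict per item with sound evidence", {
  b <- generate_patient(generation_profile(11))
  ann <- annotate_record(b$record, b$lexicon, NULL, default_negation_rules())
  res <- screen_patient(b$checklist, b$record, ann)
  expect_length(res$verdicts, length(b$checklist$items))
  expect_identical(vapply(res$verdicts, function(v) v$criterion_label,
                          character(1)),
                   vapply(b$checklist$items, function(it) it$label,
                          character(1)))
  doc_ids <- vapply(b$record$documents, function(d) d$doc_id, character(1))
  expect_true(all(res$relevant_docs %in% doc_ids))
  for (v in res$verdicts) {
    for (e in v$evidence) {
      if (e$type == "annotation") {
        expect_true(e$doc_id %in% doc_ids)
      } else {
        expect_true(e$row >= 1 && e$row <= nrow(b$record$labs))
      }
    }
  }
  # empty checklist -> empty verdict list
  empty <- screen_patient(checklist("t", "1", list()), b$record, ann)
  expect_length(empty$verdicts, 0)
  expect_length(empty$relevant_docs, 0)
})

test_that("MET leaf verdicts always carry evidence", {
  set.seed(88)
  lex <- default_lexicon()
  rules <- default_negation_rules()
  for (rep in 1:15) {
    rec <- random_small_record(lex)
    ann <- annotate_record(rec, lex, NULL, rules)
    leaf <- random_leaf("L", lex)
    v <- eval_expr(leaf, rec, ann)
    if (v$status == "MET") expect_gt(length(v$evidence), 0)
  }
})

test_that("adding an affirmed qualifying document never retracts MET", {
  set.seed(89)
  lex <- default_lexicon()
  rules <- default_negation_rules()
  crit <- hi_crit()
  for (rep in 1:15) {
    rec <- random_small_record(lex)
    ann <- annotate_record(rec, lex, NULL, rules)
    before <- eval_concept_criterion(crit, rec, ann)$status
    extra <- clinical_document("dxx", "outpatient note",
                               rec$index_time - 30 * 86400,
                               "Documented head injury this visit.")
    rec2 <- patient_record(rec$patient_id, rec$index_time,
                           c(rec$documents, list(extra)), rec$labs)
    ann2 <- annotate_record(rec2, lex, NULL, rules)
    after <- eval_concept_criterion(crit, rec2, ann2)$status
    expect_identical(after, "MET")
    if (before == "MET") expect_identical(after, "MET")
  }
})
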