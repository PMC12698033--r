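mini_lexicon <- function() {
  lexicon(data.frame(
    cui = c("C_AC", "C_AC", "C_HI", "C_HI", "C_HEAD", "C_APTT", "C_DIZZ"),
    preferred_name = c("Anticoagulant", "Anticoagulant", "Head injury",
                       "Head injury", "Headache", "APTT", "Dizziness"),
    semantic_types = c("Pharmacologic Substance", "Pharmacologic Substance",
                       "Disorder", "Disorder", "Disorder", "Laboratory",
                       "Finding"),
    surface_form = c("warfarin", "apixaban", "head injury", "head",
                     "headache", "aPTT", "dizziness"),
    case_sensitive = FALSE, stringsAsFactors = FALSE))
}

doc_of <- function(text) {
  clinical_document("doc1", "outpatient note", "2024-01-01T00:00:00Z", text)
}

test_that("drug-class surface forms tag to the class CUI", {
  ann <- tag_document(doc_of("started on warfarin yesterday"), mini_lexicon())
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$cui, "C_AC")
  expect_identical(ann$matched_text, "warfarin")
  expect_identical(ann$preferred_name, "Anticoagulant")
})

test_that("abbreviation forms match and annotations carry spans and types", {
  ann <- tag_document(doc_of("aPTT prolonged"), mini_lexicon())
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$cui, "C_APTT")
  expect_identical(ann$start, 0L)
  expect_identical(ann$end, 4L)
  expect_identical(ann$semantic_type, "Laboratory")
})

test_that("longest match wins over a shorter overlapping candidate", {
  ann <- tag_document(doc_of("prior head injury noted"), mini_lexicon())
  expect_identical(ann$matched_text, "head injury")
  expect_identical(nrow(ann), 1L)
  # but the short form still matches alone
  ann2 <- tag_document(doc_of("hit his head today"), mini_lexicon())
  expect_identical(ann2$matched_text, "head")
})

test_that("matching is token-boundary aware and case-flag aware", {
  expect_identical(nrow(tag_document(doc_of("warfarinized"), mini_lexicon())),
                   0L)
  expect_identical(nrow(tag_document(doc_of("forehead pain"), mini_lexicon())),
                   0L)
  expect_identical(tag_document(doc_of("WARFARIN held"),
                                mini_lexicon())$cui, "C_AC")
  cs_lex <- lexicon(data.frame(cui = "C_ICH", preferred_name = "ICH",
                               semantic_types = "Disorder",
                               surface_form = "ICH", case_sensitive = TRUE,
                               stringsAsFactors = FALSE))
  expect_identical(nrow(tag_document(doc_of("rich history"), cs_lex)), 0L)
  expect_identical(nrow(tag_document(doc_of("ich bin"), cs_lex)), 0L)
  expect_identical(nrow(tag_document(doc_of("prior ICH seen"), cs_lex)), 1L)
})

test_that("ambiguous forms map to the first-declared entry with a warning", {
  amb <- lexicon(data.frame(
    cui = c("C_A", "C_B"), preferred_name = c("First", "Second"),
    semantic_types = c("Disorder", "Finding"),
    surface_form = c("cold", "cold"), case_sensitive = FALSE,
    stringsAsFactors = FALSE))
  expect_warning(ann <- tag_document(doc_of("caught a cold"), amb),
                 "ambiguous")
  expect_identical(ann$cui, "C_A")
})

test_that("semantic-type filtering keeps exactly the allowed types in order", {
  ann <- tag_document(doc_of("warfarin for headache and dizziness"),
                      mini_lexicon())
  expect_identical(nrow(ann), 3L)
  kept <- filter_semantic_types(ann, "Disorder")
  expect_identical(kept$cui, "C_HEAD")
  expect_identical(nrow(filter_semantic_types(ann, character(0))), 0L)
  expect_identical(filter_semantic_types(ann, unique(ann$semantic_type)), ann)
})

test_that("pre-trigger negation scopes forward until a terminator", {
  rules <- negation_rules(pre_triggers = c("no history of", "denies", "no"),
                          terminators = c("but", "."), scope_window = 6)
  d1 <- doc_of("no history of head injury")
  a1 <- detect_negation(d1$text, tag_document(d1, mini_lexicon()), rules)
  expect_true(a1$negated)

  d2 <- doc_of("denies headache but reports dizziness")
  a2 <- detect_negation(d2$text, tag_document(d2, mini_lexicon()), rules)
  expect_identical(a2$negated[a2$cui == "C_HEAD"], TRUE)
  expect_identical(a2$negated[a2$cui == "C_DIZZ"], FALSE)

  # sentence boundary blocks the trigger
  d3 <- doc_of("denies fever. headache persists")
  a3 <- detect_negation(d3$text, tag_document(d3, mini_lexicon()), rules)
  expect_false(a3$negated)

  # beyond the scope window the trigger has no effect
  d4 <- doc_of("no acute events were recorded over months preceding headache")
  a4 <- detect_negation(d4$text, tag_document(d4, mini_lexicon()), rules)
  expect_false(a4$negated)
})

test_that("post-triggers scope backward and no triggers means no negation", {
  rules <- negation_rules(pre_triggers = "no",
                          post_triggers = "was ruled out",
                          terminators = ".", scope_window = 6)
  d <- doc_of("head injury was ruled out today")
  a <- detect_negation(d$text, tag_document(d, mini_lexicon()), rules)
  expect_true(a$negated)
  d2 <- doc_of("head injury documented today")
  a2 <- detect_negation(d2$text, tag_document(d2, mini_lexicon()), rules)
  expect_false(a2$negated)
})

test_that("tagging is deterministic and spans are faithful under fuzzing", {
  set.seed(77)
  lex <- default_lexicon()
  rules <- default_negation_rules()
  for (rep in 1:25) {
    rec <- random_small_record(lex)
    a1 <- annotate_record(rec, lex, NULL, rules)
    a2 <- annotate_record(rec, lex, NULL, rules)
    expect_identical(a1, a2)
    for (doc in rec$documents) {
      ann <- a1[[doc$doc_id]]
      for (i in seq_len(nrow(ann))) {
        expect_identical(substring(doc$text, ann$start[i] + 1L, ann$end[i]),
                         ann$matched_text[i])
      }
    }
  }
})

test_that("planted mentions are recovered with their planted polarity", {
  b <- generate_patient(generation_profile(123))
  ann <- combine_annotations(annotate_record(b$record, b$lexicon, NULL,
                                             default_negation_rules()))
  key <- function(df) paste(df$doc_id, df$start, df$end, df$cui, df$negated)
  expect_setequal(key(ann), key(b$gold))
  expect_identical(sum(ann$negated), sum(b$gold$negated))
})

test_that("pipeline equals manual composition of tag, filter, negate", {
  lex <- default_lexicon()
  rules <- default_negation_rules()
  b <- generate_patient(generation_profile(5, n_documents = 4L))
  rec <- b$record
  auto <- annotate_record(rec, lex, "Disorder", rules)
  manual <- lapply(rec$documents, function(doc) {
    detect_negation(doc$text,
                    filter_semantic_types(tag_document(doc, lex), "Disorder"),
                    rules)
  })
  names(manual) <- vapply(rec$documents, function(d) d$doc_id, character(1))
  expect_identical(auto, manual)
  empty <- annotate_record(patient_record("p", "2024-01-01"), lex)
  expect_identical(length(empty), 0L)
})
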