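test_that("DSL parses lab, ratio and disjunctive concept criteria", {
  cl <- parse_dsl(c(
    'trial "demo"',
    'exclusion "plt": lab "Platelets" < 100000',
    'exclusion "aptt": lab "APTT" <= 1.4 x control within 7 days before index',
    'exclusion "ha": (concept "Headache" in [outpatient note, admission note] within 3 years before index) or (concept "Head injury" in [outpatient note, admission note] within 3 years before index)'))
  expect_s3_class(cl, "eligibility_checklist")
  expect_length(cl$items, 3)

  plt <- cl$items[[1]]$expr$payload
  expect_identical(plt$comparator, "LT")
  expect_identical(plt$threshold, 100000)
  expect_identical(plt$mode, "ABSOLUTE")
  expect_null(plt$window)

  aptt <- cl$items[[2]]$expr$payload
  expect_identical(aptt$comparator, "LE")
  expect_identical(aptt$threshold, 1.4)
  expect_identical(aptt$mode, "RATIO_TO_CONTROL")
  expect_identical(aptt$window,
                   temporal_window(7, "DAYS", "BEFORE_INDEX"))

  ha <- cl$items[[3]]$expr
  expect_identical(ha$kind, "OR")
  expect_length(ha$children, 2)
  expect_identical(ha$children[[1]]$payload$concepts$preferred_name,
                   "Headache")
  expect_identical(ha$children[[1]]$payload$window,
                   temporal_window(3, "YEARS"))
  expect_setequal(ha$children[[2]]$payload$doc_types,
                  c("outpatient note", "admission note"))
})

test_that("DSL errors carry position, resolution and no-items diagnostics", {
  expect_error(parse_dsl('exclusion "x": lab "A" <'), "line 1")
  expect_error(parse_dsl('exclusion "x": lab "A" < 5 garbage'),
               "trailing tokens")
  expect_error(parse_dsl('exclusion "x": concept "A" in []'),
               "document type")
  expect_error(parse_dsl('trial "t"'), "no checklist items")
  expect_error(
    parse_dsl('exclusion "x": concept "Nonexistent" in [er note]',
              lexicon = default_lexicon()),
    "resolution error.*Nonexistent")
  expect_error(
    parse_dsl('exclusion "x": lab "Mystery" < 5',
              lab_items = c("Platelets")),
    "resolution error.*Mystery")
})

test_that("concept names resolve against a lexicon by name or surface form", {
  lex <- default_lexicon()
  cl <- parse_dsl('exclusion "w": concept "warfarin" in [outpatient note]',
                  lexicon = lex)
  expect_identical(cl$items[[1]]$expr$payload$concepts$cui, "C0003280")
  expect_identical(cl$items[[1]]$expr$payload$concepts$preferred_name,
                   "Anticoagulant")
})

test_that("validate_expr reports arity, positivity and enum violations", {
  ok <- rule_and(lab_criterion("a", "Platelets", "LT", 100000),
                 concept_criterion("b", c(Headache = "C1"), "outpatient note"))
  expect_identical(nrow(validate_expr(ok)), 0L)

  bad_and <- ok
  bad_and$children <- ok$children[1]
  v <- validate_expr(bad_and)
  expect_match(v$message, "AND requires >= 2 children", all = FALSE)

  bad_ratio <- rule_leaf(lab_criterion("r", "APTT", "LE", 1.4,
                                       mode = "RATIO_TO_CONTROL"))
  bad_ratio$payload$threshold <- -1
  v <- validate_expr(bad_ratio)
  expect_match(v$message, "RATIO_TO_CONTROL threshold", all = FALSE)
  expect_identical(v$path, "expr")
})

test_that("single-field mutations of valid trees are each caught", {
  base <- rule_or(
    lab_criterion("a", "APTT", "GT", 1.4, mode = "RATIO_TO_CONTROL",
                  window = temporal_window(7, "DAYS")),
    concept_criterion("b", c(Stroke = "C0038454"), "er note",
                      window = temporal_window(3, "YEARS")))
  expect_identical(nrow(validate_expr(base)), 0L)

  mutations <- list(
    function(e) { e$children[[1]]$payload$comparator <- "APPROX"; e },
    function(e) { e$children[[1]]$payload$threshold <- Inf; e },
    function(e) { e$children[[1]]$payload$mode <- "RELATIVE"; e },
    function(e) { e$children[[1]]$payload$window$amount <- 0L; e },
    function(e) { e$children[[1]]$payload$window$unit <- "WEEKS"; e },
    function(e) { e$children[[2]]$payload$doc_types <- character(0); e },
    function(e) { e$children[[2]]$payload$concepts <-
      e$children[[2]]$payload$concepts[0, ]; e },
    function(e) { e$children <- e$children[1]; e },
    function(e) { e$kind <- "XOR"; e })
  for (mut in mutations) {
    expect_gt(nrow(validate_expr(mut(base))), 0)
  }
})

test_that("rule files round-trip and reject unknown versions and fields", {
  set.seed(401)
  cl <- random_checklist()
  js <- serialize_checklist(cl)
  cl2 <- deserialize_checklist(js)
  expect_identical(cl2, cl)
  expect_identical(serialize_checklist(cl2), js)

  bad <- sub('"schema_version": "1.0"', '"schema_version": "99"', js,
             fixed = TRUE)
  expect_error(deserialize_checklist(bad), "unknown rule-file schema version")

  extra <- sub('"schema_version"', '"surprise": 1, "schema_version"', js,
               fixed = TRUE)
  expect_error(deserialize_checklist(extra), "unknown field")
})

test_that("serialization and DSL round trips hold over generated checklists", {
  set.seed(402)
  for (rep in 1:60) {
    cl <- random_checklist()
    expect_identical(deserialize_checklist(serialize_checklist(cl)), cl)
    expect_identical(parse_dsl(pretty_print(cl)), cl)
  }
})

test_that("an eleven-item checklist survives file round trip intact", {
  cl <- demo_checklist()
  expect_length(cl$items, 11)
  path <- withr::local_tempfile(fileext = ".json")
  write_checklist(cl, path)
  cl2 <- read_checklist(path)
  expect_length(cl2$items, 11)
  expect_identical(cl2, cl)
  expect_identical(nrow(validate_checklist(cl)), 0L)
  # DSL round trip in the same lexicon context
  expect_identical(parse_dsl(pretty_print(cl), lexicon = default_lexicon()),
                   cl)
})

test_that("checklist constructor rejects duplicate labels; empty one is flagged", {
  it <- checklist_item("dup", "INCLUSION",
                       lab_criterion("a", "INR", "GT", 1.7))
  expect_error(checklist("t", "1", list(it, it)), "duplicate item label")
  v <- validate_checklist(checklist("t", "1", list()))
  expect_match(v$message, ">= 1 item", all = FALSE)
})
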