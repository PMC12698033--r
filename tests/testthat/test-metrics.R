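pred_row <- function(doc_id, start, end, cui, negated = FALSE) {
  data.frame(doc_id = doc_id, start = as.integer(start), end = as.integer(end),
             matched_text = "x", cui = cui, preferred_name = cui,
             semantic_type = "Disorder", negated = negated,
             stringsAsFactors = FALSE)
}

test_that("a 1-TP / 4-FP / 0-FN concept scores F1 = 1/3", {
  gold <- gold_annotations("d1", 10L, 18L, "C_AC", FALSE)
  pred <- rbind(pred_row("d1", 10, 18, "C_AC"),
                pred_row("d1", 30, 38, "C_AC"),
                pred_row("d1", 50, 58, "C_AC"),
                pred_row("d2", 5, 13, "C_AC"),
                pred_row("d2", 40, 48, "C_AC"))
  r <- concept_prf(pred, gold)
  expect_identical(r$tp, 1L)
  expect_identical(r$fp, 4L)
  expect_identical(r$fn, 0L)
  expect_equal(r$precision, 0.2)
  expect_equal(r$recall, 1.0)
  expect_equal(r$f1, 1 / 3)
})

test_that("perfect, empty and negated predictions score as defined", {
  gold <- gold_annotations(c("d1", "d1"), c(0L, 20L), c(5L, 28L),
                           c("C_A", "C_B"), c(FALSE, FALSE))
  pred <- rbind(pred_row("d1", 0, 5, "C_A"), pred_row("d1", 20, 28, "C_B"))
  r <- concept_prf(pred, gold)
  expect_true(all(r$precision == 1 & r$recall == 1 & r$f1 == 1))

  r0 <- concept_prf(pred_row("d?", 1, 2, "C_A")[0, ], gold)
  expect_true(all(r0$recall == 0))
  expect_true(all(is.na(r0$precision)))  # zero denominator reported as n/a

  # negated predictions do not count as detections
  neg <- rbind(pred_row("d1", 0, 5, "C_A", negated = TRUE))
  rn <- concept_prf(neg, gold_annotations("d1", 0L, 5L, "C_A", FALSE))
  expect_identical(rn$tp, 0L)
  expect_identical(rn$fp, 0L)
  expect_identical(rn$fn, 1L)
})

test_that("overlap and exact span policies differ as specified", {
  gold <- gold_annotations("d1", 10L, 20L, "C_A", FALSE)
  shifted <- pred_row("d1", 15, 25, "C_A")
  expect_identical(concept_prf(shifted, gold, policy = "overlap")$tp, 1L)
  expect_identical(concept_prf(shifted, gold, policy = "exact")$tp, 0L)
  # adjacent half-open spans do not overlap
  adjacent <- pred_row("d1", 20, 30, "C_A")
  expect_identical(concept_prf(adjacent, gold, policy = "overlap")$tp, 0L)
})

test_that("gold referencing unknown documents is an error", {
  gold <- gold_annotations("ghost", 0L, 3L, "C_A", FALSE)
  expect_error(concept_prf(pred_row("d1", 0, 3, "C_A"), gold,
                           doc_ids = "d1"),
               "unknown doc_id.*ghost")
})

test_that("concept_prf equals the exhaustive matcher on random instances", {
  set.seed(66)
  for (rep in 1:50) {
    n_p <- sample(0:10, 1)
    n_g <- sample(0:10, 1)
    cuis <- c("C_A", "C_B", "C_C")
    docs <- c("d1", "d2")
    mk <- function(n) {
      s <- sample(0:50, n, replace = TRUE)
      data.frame(doc_id = sample(docs, n, replace = TRUE),
                 start = as.integer(s), end = as.integer(s + sample(1:8, n,
                                                                    replace = TRUE)),
                 cui = sample(cuis, n, replace = TRUE),
                 negated = runif(n) < 0.2, stringsAsFactors = FALSE)
    }
    g <- mk(n_g)
    p <- mk(n_p)
    p$matched_text <- rep("x", nrow(p))
    p$preferred_name <- p$cui
    p$semantic_type <- rep("Disorder", nrow(p))
    policy <- sample(c("overlap", "exact"), 1)
    got <- concept_prf(p, gold_annotations(g$doc_id, g$start, g$end, g$cui,
                                           g$negated), policy = policy)
    want <- oracle_prf(p, g, policy = policy)
    expect_identical(nrow(got), length(want))
    for (i in seq_len(nrow(got))) {
      w <- want[[got$cui[i]]]
      expect_identical(c(tp = got$tp[i], fp = got$fp[i], fn = got$fn[i]), w)
    }
  }
})

test_that("deleting k of n planted lexicon forms cuts recall to (n-k)/n", {
  b <- generate_patient(generation_profile(321, distractor_density = 0,
                                           planted_facts = data.frame(
    cui = rep("C0003280", 4), polarity = "affirmed",
    doc_type = "outpatient note", offset_days = c(-2, -30, -60, -150),
    stringsAsFactors = FALSE)))
  rules <- default_negation_rules()
  full <- concept_prf(annotate_record(b$record, b$lexicon, NULL, rules),
                      b$gold)
  expect_equal(full[full$cui == "C0003280", "recall"], 1.0)
  n <- 4L
  # drop the surface forms actually planted in k of the documents
  planted_forms <- vapply(seq_len(nrow(b$gold)), function(i) {
    doc <- Filter(function(d) d$doc_id == b$gold$doc_id[i],
                  b$record$documents)[[1]]
    substring(doc$text, b$gold$start[i] + 1L, b$gold$end[i])
  }, character(1))
  for (k in 1:2) {
    drop <- unique(tolower(planted_forms))[seq_len(k)]
    # removing a form may orphan several mentions; recompute exactly
    lex2 <- b$lexicon[!(tolower(b$lexicon$surface_form) %in% drop), ]
    class(lex2) <- class(b$lexicon)
    r <- concept_prf(annotate_record(b$record, lex2, NULL, rules), b$gold)
    lost <- sum(tolower(planted_forms) %in% drop)
    expect_equal(r[r$cui == "C0003280", "recall"], (n - lost) / n)
  }
})

test_that("checklist accuracy is the mean of per-criterion correctness", {
  ref <- rep("yes", 11)
  resp <- ref
  resp[4] <- "no"
  got <- checklist_accuracy(resp, ref)
  expect_identical(got$n_items, 11L)
  expect_identical(got$n_correct, 10L)
  expect_equal(round(got$accuracy, 4), 0.9091)
  expect_equal(checklist_accuracy(ref, ref)$accuracy, 1)
  expect_equal(checklist_accuracy(rep("no", 11), ref)$accuracy, 0)
  expect_error(checklist_accuracy(ref[-1], ref), "same length")
})

test_that("NASA-TLX maps weighted 0-20 ratings onto 0-100", {
  w <- c(5, 4, 3, 2, 1, 0)
  expect_equal(nasa_tlx_score(rep(20, 6), w)$score, 100)
  expect_equal(nasa_tlx_score(rep(0, 6), w)$score, 0)
  # constant ratings are invariant to any valid weighting
  for (weights in list(c(5, 4, 3, 2, 1, 0), c(3, 3, 3, 2, 2, 2),
                       c(15, 0, 0, 0, 0, 0))) {
    expect_equal(nasa_tlx_score(rep(10, 6), weights)$score, 50)
  }
  raw <- nasa_tlx_score(rep(10, 6))
  expect_equal(raw$score, 50)
  expect_identical(raw$weighting, "raw")
  expect_error(nasa_tlx_score(rep(21, 6), w), "\\[0, 20\\]")
  expect_error(nasa_tlx_score(rep(10, 6), c(5, 4, 3, 2, 1, 2)), "summing to 15")
})

test_that("SUS scores the alternating 10-item questionnaire onto 0-100", {
  best <- c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1)
  worst <- c(1, 5, 1, 5, 1, 5, 1, 5, 1, 5)
  expect_equal(sus_score(best), 100)
  expect_equal(sus_score(worst), 0)
  expect_equal(sus_score(rep(3, 10)), 50)
  expect_error(sus_score(rep(3, 9)), "10 responses")
  expect_error(sus_score(c(rep(3, 9), 6)), "1\\.\\.5")
})

test_that("instrument scores are monotone in each response", {
  set.seed(9)
  for (rep in 1:20) {
    r <- runif(6, 0, 20)
    w <- c(5, 4, 3, 2, 1, 0)
    i <- sample(6, 1)
    r2 <- r
    r2[i] <- min(20, r[i] + runif(1, 0, 5))
    expect_gte(nasa_tlx_score(r2, w)$score, nasa_tlx_score(r, w)$score)

    s <- sample(1:5, 10, replace = TRUE)
    odd <- sample(c(1, 3, 5, 7, 9), 1)
    s_up <- s
    s_up[odd] <- min(5, s[odd] + 1)
    expect_gte(sus_score(s_up), sus_score(s))
    even <- sample(c(2, 4, 6, 8, 10), 1)
    s_up2 <- s
    s_up2[even] <- min(5, s[even] + 1)
    expect_lte(sus_score(s_up2), sus_score(s))
  }
})
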