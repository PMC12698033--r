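#' @title Synthetic EMR generator
#' @description Deterministic generator of synthetic patient bundles with
#'   known ground truth: multi-department note streams with criteria-relevant
#'   concepts planted affirmatively and under negation, distractor mentions,
#'   lab series including ratio-to-control items, and critical facts that can
#'   be buried in less prominent note types (outpatient notes). Gold spans
#'   and expected per-criterion verdicts are computed at generation time from
#'   the planted-fact table — never by running the engine under test — so
#'   every pipeline stage can be validated end to end without real records.
#' @name synthetic_emr
NULL

#' Shipped demonstration lexicon
#'
#' Concepts relevant to thrombolysis-style eligibility screening plus
#' deliberate distractor concepts. The broad Anticoagulant class is one CUI
#' whose surface forms enumerate individual drugs (warfarin, apixaban,
#' dabigatran, edoxaban, rivaroxaban) — the enumeration workaround for
#' engines that cannot generalize drug classes, promoted to a first-class
#' lexicon feature.
#'
#' @return a [lexicon()].
#' @export
default_lexicon <- function() {
  row <- function(cui, name, types, forms, cs = FALSE) {
    data.frame(cui = cui, preferred_name = name, semantic_types = types,
               surface_form = forms,
               case_sensitive = rep_len(cs, length(forms)),
               stringsAsFactors = FALSE)
  }
  lexicon(rbind(
    row("C0018681", "Headache", "Disorder",
        c("headache", "headaches", "cephalalgia")),
    row("C0018674", "Head injury", "Disorder",
        c("head injury", "head trauma", "traumatic brain injury")),
    row("C0011849", "Diabetes mellitus", "Disorder",
        c("diabetes", "diabetes mellitus", "type 2 diabetes")),
    row("C0038454", "Stroke", "Disorder",
        c("stroke", "ischemic stroke", "cerebral infarction")),
    row("C0038454", "Stroke", "Disorder", "CVA", cs = TRUE),
    row("C0151699", "Intracranial hemorrhage", "Disorder",
        c("intracranial hemorrhage", "intracerebral hemorrhage",
          "brain hemorrhage")),
    row("C0151699", "Intracranial hemorrhage", "Disorder", "ICH", cs = TRUE),
    row("C0019080", "Internal bleeding", "Disorder",
        c("internal bleeding", "gastrointestinal bleeding", "GI bleeding",
          "hematemesis")),
    row("C0003280", "Anticoagulant", "Pharmacologic Substance",
        c("anticoagulant", "warfarin", "apixaban", "dabigatran", "edoxaban",
          "rivaroxaban")),
    row("C0038895", "Major surgery", "Procedure",
        c("major surgery", "laparotomy", "craniotomy")),
    row("C0036572", "Seizure", "Disorder", c("seizure", "convulsion")),
    row("C0007787", "Transient ischemic attack", "Disorder",
        "transient ischemic attack"),
    row("C0020538", "Hypertension", "Disorder",
        c("hypertension", "high blood pressure")),
    row("C0020473", "Hyperlipidemia", "Disorder", "hyperlipidemia"),
    row("C0004057", "Aspirin", "Pharmacologic Substance", "aspirin"),
    row("C0010200", "Cough", "Finding", "cough")))
}

#' Shipped negation rule set
#'
#' Trigger/scope rules with a 6-token scope window. Sentence punctuation
#' terminates scopes, as do contrastive conjunctions ("but", "however").
#'
#' @return a [negation_rules()].
#' @export
default_negation_rules <- function() {
  negation_rules(
    pre_triggers = c("no", "not", "denies", "denied", "without",
                     "no history of", "no evidence of", "negative for",
                     "never had", "free of", "rules out", "ruled out"),
    post_triggers = c("was ruled out", "is ruled out", "not present",
                      "was negative", "is unlikely"),
    terminators = c("but", "however", "although", "except", "besides",
                    ".", ";", ":", "?", "!"),
    scope_window = 6L)
}

demo_doc_types <- function() {
  c("admission note", "outpatient note", "discharge summary", "er note",
    "nursing note", "radiology report")
}

concept_ref <- function(lex, cui) {
  i <- match(cui, lex$cui)
  data.frame(cui = cui, preferred_name = lex$preferred_name[i],
             stringsAsFactors = FALSE)
}

#' Demonstration eligibility checklist
#'
#' An eleven-item thrombolysis-style exclusion checklist exercising every
#' rule feature: absolute and ratio-to-control lab thresholds, day / month /
#' year windows, document-type selection, disjunctive concept criteria, and
#' a cross-document conjunction ("diabetes with prior stroke").
#'
#' @param lex lexicon used to resolve concept names (default shipped one).
#' @return an `eligibility_checklist`.
#' @export
demo_checklist <- function(lex = default_lexicon()) {
  cc <- function(id, cui, doc_types, window = NULL)
    concept_criterion(id, concept_ref(lex, cui), doc_types, window)
  hist_types <- c("admission note", "outpatient note", "discharge summary")
  checklist("rt-PA style demonstration trial", "1", list(
    checklist_item("Platelet count below 100,000 per mm3", "EXCLUSION",
                   lab_criterion("c1_1", "Platelets", "LT", 100000)),
    checklist_item("Blood glucose below 50 mg/dL", "EXCLUSION",
                   lab_criterion("c2_1", "Glucose", "LT", 50, unit = "mg/dL")),
    checklist_item("APTT above 1.4 times control within 7 days", "EXCLUSION",
                   lab_criterion("c3_1", "APTT", "GT", 1.4,
                                 mode = "RATIO_TO_CONTROL",
                                 window = temporal_window(7, "DAYS"))),
    checklist_item("INR above 1.7", "EXCLUSION",
                   lab_criterion("c4_1", "INR", "GT", 1.7)),
    checklist_item("Prior intracranial hemorrhage", "EXCLUSION",
                   cc("c5_1", "C0151699",
                      c("radiology report", "discharge summary"))),
    checklist_item("Head trauma or stroke within 3 months", "EXCLUSION",
                   rule_or(cc("c6_1", "C0018674", hist_types,
                              temporal_window(3, "MONTHS")),
                           cc("c6_2", "C0038454", hist_types,
                              temporal_window(3, "MONTHS")))),
    checklist_item("Internal bleeding within 3 months", "EXCLUSION",
                   cc("c7_1", "C0019080",
                      c("admission note", "outpatient note", "er note"),
                      temporal_window(3, "MONTHS"))),
    checklist_item("Major surgery within 14 days", "EXCLUSION",
                   cc("c8_1", "C0038895", hist_types,
                      temporal_window(14, "DAYS"))),
    checklist_item("Headache or head injury within 3 years", "EXCLUSION",
                   rule_or(cc("c9_1", "C0018681",
                              c("outpatient note", "admission note"),
                              temporal_window(3, "YEARS")),
                           cc("c9_2", "C0018674",
                              c("outpatient note", "admission note"),
                              temporal_window(3, "YEARS")))),
    checklist_item("Current anticoagulant use", "EXCLUSION",
                   cc("c10_1", "C0003280",
                      c("outpatient note", "admission note"),
                      temporal_window(6, "MONTHS"))),
    checklist_item("History of diabetes with prior stroke", "EXCLUSION",
                   rule_and(cc("c11_1", "C0011849", hist_types),
                            cc("c11_2", "C0038454", hist_types)))))
}

#' Generation profile
#'
#' Describes one synthetic patient. Facts are planted at signed day offsets
#' from the index time (negative = before). With `planted_facts = NULL` a
#' randomized but seed-deterministic set of facts and labs is drawn; offsets
#' are then confined to values far from every window boundary of the target
#' checklist so ground-truth derivation is unambiguous.
#'
#' @param seed integer; same seed and profile give byte-identical output.
#' @param n_documents total documents (planted-fact documents plus filler).
#' @param doc_type_mix named numeric vector of filler doc-type weights.
#' @param planted_facts data frame with columns `cui`, `polarity`
#'   ("affirmed"/"negated"), `doc_type`, `offset_days` (signed), or `NULL`.
#' @param distractor_density mean number of distractor-concept mentions per
#'   filler document (>= 0).
#' @param lab_series list of `list(item, value, unit, control_value,
#'   offset_days)` rows, or `NULL` to randomize.
#' @param bury_in_outpatient plant one critical contraindication
#'   (anticoagulant use) only in an outpatient note.
#' @param index_time ISO-8601 index time.
#' @return object of class `generation_profile`.
#' @export
generation_profile <- function(seed, n_documents = 10L,
                               doc_type_mix = NULL, planted_facts = NULL,
                               distractor_density = 1.5, lab_series = NULL,
                               bury_in_outpatient = FALSE,
                               index_time = "2024-06-15T10:30:00Z") {
  if (is.null(doc_type_mix)) {
    doc_type_mix <- stats::setNames(c(2, 3, 2, 1, 2, 1), demo_doc_types())
  }
  stopifnot(distractor_density >= 0, n_documents >= 1L)
  structure(list(seed = as.integer(seed), n_documents = as.integer(n_documents),
                 doc_type_mix = doc_type_mix, planted_facts = planted_facts,
                 distractor_density = distractor_density,
                 lab_series = lab_series,
                 bury_in_outpatient = isTRUE(bury_in_outpatient),
                 index_time = index_time),
            class = "generation_profile")
}

# Offsets (days before index) at least a week away from every demo-checklist
# window boundary (7, 14, ~91, ~183, ~1096 days), so that the generator's
# day-based window arithmetic and the engine's calendar arithmetic agree on
# membership for every planted fact.
SAFE_OFFSETS <- c(-2, -30, -60, -150, -400, -700, -1400)

unit_days <- c(DAYS = 1, MONTHS = 30.44, YEARS = 365.25)

offset_in_window <- function(offset_days, window) {
  if (is.null(window)) return(TRUE)
  w <- window$amount * unit_days[[window$unit]]
  if (window$direction == "BEFORE_INDEX") offset_days >= -w & offset_days < 0
  else offset_days >= 0 & offset_days < w
}

# --- narrative templates ----------------------------------------------------
# Boilerplate must not contain any lexicon surface form or negation trigger.

tpl_intro <- c("Patient seen and examined today.",
               "Routine follow-up visit.",
               "Chart reviewed in detail.")
tpl_filler <- c("Vital signs within normal limits.",
                "Medication list reviewed with the patient.",
                "Plan discussed and questions answered.",
                "Will continue current management.",
                "Laboratory results reviewed.",
                "Family present at bedside.")
tpl_affirmed <- c("Known %s in the medical record.",
                  "History of %s documented.",
                  "Assessment notes %s at this visit.")
tpl_negated <- c("The patient denies %s at this time.",
                 "No history of %s in the chart.",
                 "There is no %s on review.",
                 "Screening negative for %s.")

pick <- function(x) x[[sample.int(length(x), 1L)]]

# Append one sentence carrying a mention; returns list(sentence, form_offset)
mention_sentence <- function(form, negated) {
  tpl <- if (negated) pick(tpl_negated) else pick(tpl_affirmed)
  at <- regexpr("%s", tpl, fixed = TRUE)[1]
  list(sentence = sub("%s", form, tpl, fixed = TRUE),
       form_offset = at - 1L)
}

surface_for <- function(lex, cui) {
  forms <- lex$surface_form[lex$cui == cui]
  pick(forms)
}

checklist_cuis <- function(expr) {
  if (expr$kind == "CONCEPT") return(expr$payload$concepts$cui)
  if (expr$kind == "LAB") return(character(0))
  unique(unlist(lapply(expr$children, checklist_cuis)))
}

checklist_all_cuis <- function(cl) {
  unique(unlist(lapply(cl$items, function(it) checklist_cuis(it$expr))))
}

# --- randomized default content --------------------------------------------

random_facts <- function(cl, lex) {
  cuis <- checklist_all_cuis(cl)
  rows <- list()
  fact_types <- c("admission note", "outpatient note", "discharge summary",
                  "er note")
  for (cui in cuis) {
    r <- stats::runif(1)
    if (r < 0.45) next                       # concept absent
    polarity <- if (r < 0.75) "affirmed" else "negated"
    rows[[length(rows) + 1L]] <- data.frame(
      cui = cui, polarity = polarity,
      doc_type = pick(fact_types),
      offset_days = pick(SAFE_OFFSETS), stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(cui = character(0), polarity = character(0),
                  doc_type = character(0), offset_days = numeric(0),
                  stringsAsFactors = FALSE)
}

random_labs <- function() {
  rows <- list()
  add <- function(item, value, unit, control, offset) {
    rows[[length(rows) + 1L]] <<- list(item = item, value = value,
                                       unit = unit, control_value = control,
                                       offset_days = offset)
  }
  if (stats::runif(1) < 0.9)
    add("Platelets", pick(c(60000, 150000, 250000)), "per mm3", NA, -1)
  if (stats::runif(1) < 0.9)
    add("Glucose", pick(c(40, 95, 130)), "mg/dL", NA, -1)
  if (stats::runif(1) < 0.9)
    add("INR", pick(c(1.0, 1.2, 2.5)), "", NA, -2)
  r <- stats::runif(1)
  if (r < 0.4) {
    add("APTT", 30 * pick(c(1.0, 1.2, 1.8)), "s", 30, -2)
  } else if (r < 0.6) {
    add("APTT", 30 * pick(c(1.0, 1.8)), "s", NA, -2)  # control missing
  } else if (r < 0.8) {
    add("APTT", 30 * 1.8, "s", 30, -10)               # outside 7-day window
  }
  rows
}

# --- ground-truth derivation (independent of the inference engine) ----------
# Statuses are computed on the planted-fact table with the numeric Kleene
# encoding NOT_MET = 0 < UNKNOWN = 1 < MET = 2: AND = min, OR = max,
# NOT = 2 - x.

derive_lab_status <- function(crit, labs) {
  idx <- which(vapply(labs, function(l) identical(l$item, crit$lab_item$code),
                      logical(1)))
  idx <- idx[vapply(labs[idx], function(l)
    offset_in_window(l$offset_days, crit$window), logical(1))]
  if (!length(idx)) return(1)  # UNKNOWN
  offs <- vapply(labs[idx], function(l) l$offset_days, numeric(1))
  i <- idx[which(offs == max(offs))]
  l <- labs[[i[length(i)]]]
  if (crit$mode == "RATIO_TO_CONTROL") {
    if (is.na(l$control_value)) return(1)
    obs <- l$value / l$control_value
  } else obs <- l$value
  if (comparator_fun(crit$comparator)(obs, crit$threshold)) 2 else 0
}

derive_concept_status <- function(crit, facts, doc_types_present) {
  if (!any(doc_types_present %in% crit$doc_types)) return(1)
  if (!nrow(facts)) return(0)
  hit <- facts$polarity == "affirmed" & facts$cui %in% crit$concepts$cui &
    facts$doc_type %in% crit$doc_types &
    vapply(seq_len(nrow(facts)), function(i)
      offset_in_window(facts$offset_days[i], crit$window), logical(1))
  if (any(hit)) 2 else 0
}

derive_status <- function(expr, facts, labs, doc_types_present) {
  switch(expr$kind,
         LAB = derive_lab_status(expr$payload, labs),
         CONCEPT = derive_concept_status(expr$payload, facts,
                                         doc_types_present),
         NOT = 2 - derive_status(expr$children[[1]], facts, labs,
                                 doc_types_present),
         AND = min(vapply(expr$children, derive_status, numeric(1),
                          facts = facts, labs = labs,
                          doc_types_present = doc_types_present)),
         OR = max(vapply(expr$children, derive_status, numeric(1),
                         facts = facts, labs = labs,
                         doc_types_present = doc_types_present)))
}

# --- generator --------------------------------------------------------------

#' Generate one synthetic patient with ground truth
#'
#' Builds a patient record whose documents embed the profile's planted facts
#' in template narrative (negated plantings use triggers from the shipped
#' negation rule set) plus distractor mentions, the lab series, the gold
#' span annotations, and expected per-criterion verdict statuses derived
#' directly from the planted facts.
#'
#' @param profile a [generation_profile()].
#' @param cl target checklist (default [demo_checklist()]).
#' @param lex lexicon the facts are drawn from (default shipped one).
#' @return a `ground_truth_bundle`: list with `record`, `lexicon`, `gold`,
#'   `expected_verdicts` (data frame label/role/status), `facts`, `profile`.
#' @export
generate_patient <- function(profile, cl = demo_checklist(),
                             lex = default_lexicon()) {
  stopifnot(inherits(profile, "generation_profile"))
  with_seed(profile$seed, {
    facts <- profile$planted_facts
    if (is.null(facts)) facts <- random_facts(cl, lex)
    if (nrow(facts) && !all(facts$cui %in% lex$cui))
      stop("planted fact references CUI absent from the lexicon: ",
           paste(setdiff(facts$cui, lex$cui), collapse = ", "), call. = FALSE)
    if (profile$bury_in_outpatient) {
      facts <- facts[!(facts$cui == "C0003280"), , drop = FALSE]
      facts <- rbind(facts, data.frame(cui = "C0003280",
                                       polarity = "affirmed",
                                       doc_type = "outpatient note",
                                       offset_days = -60,
                                       stringsAsFactors = FALSE))
    }
    labs <- profile$lab_series
    if (is.null(labs)) labs <- random_labs()

    index_time <- parse_timestamp(profile$index_time)
    relevant <- checklist_all_cuis(cl)
    safe_cuis <- setdiff(unique(lex$cui), relevant)

    docs <- list()
    mentions <- list()  # doc_id, start, end, cui, negated
    doc_no <- 0L
    add_doc <- function(doc_type, offset_days, plant) {
      # plant: NULL or list(cui, negated)
      doc_no <<- doc_no + 1L
      doc_id <- sprintf("d%03d", doc_no)
      sentences <- c(toupper(doc_type), pick(tpl_intro))
      n_lead <- sample.int(2L, 1L)
      sentences <- c(sentences, sample(tpl_filler, n_lead))
      planted <- list()
      if (!is.null(plant)) {
        form <- surface_for(lex, plant$cui)
        ms <- mention_sentence(form, plant$negated)
        planted[[1L]] <- list(sentence_index = length(sentences) + 1L,
                              cui = plant$cui, negated = plant$negated,
                              form = form, form_offset = ms$form_offset)
        sentences <- c(sentences, ms$sentence)
      }
      n_dis <- stats::rpois(1, profile$distractor_density)
      for (k in seq_len(min(n_dis, 3L))) {
        if (!length(safe_cuis)) break
        cui <- pick(safe_cuis)
        neg <- stats::runif(1) < 0.3
        form <- surface_for(lex, cui)
        ms <- mention_sentence(form, neg)
        planted[[length(planted) + 1L]] <-
          list(sentence_index = length(sentences) + 1L, cui = cui,
               negated = neg, form = form, form_offset = ms$form_offset)
        sentences <- c(sentences, ms$sentence)
      }
      sentences <- c(sentences, pick(tpl_filler))
      text <- paste(sentences, collapse = "\n")
      starts <- cumsum(c(0L, nchar(sentences, type = "chars") + 1L))
      for (p in planted) {
        s <- starts[p$sentence_index] + p$form_offset
        mentions[[length(mentions) + 1L]] <<- data.frame(
          doc_id = doc_id, start = s, end = s + nchar(p$form),
          cui = p$cui, negated = p$negated, doc_type = doc_type,
          offset_days = offset_days, stringsAsFactors = FALSE)
      }
      docs[[length(docs) + 1L]] <<- clinical_document(
        doc_id, doc_type, index_time + offset_days * 86400, text)
      doc_id
    }

    for (i in seq_len(nrow(facts))) {
      add_doc(facts$doc_type[i], facts$offset_days[i],
              list(cui = facts$cui[i],
                   negated = facts$polarity[i] == "negated"))
    }
    n_filler <- max(0L, profile$n_documents - length(docs))
    mix <- profile$doc_type_mix
    for (i in seq_len(n_filler)) {
      dt <- sample(names(mix), 1L, prob = mix)
      add_doc(dt, pick(SAFE_OFFSETS), NULL)
    }

    lab_rows <- if (length(labs)) {
      do.call(rbind, lapply(labs, function(l) {
        data.frame(item = l$item, value = l$value, unit = l$unit,
                   control_value = l$control_value,
                   timestamp = format_timestamp(index_time +
                                                  l$offset_days * 86400),
                   stringsAsFactors = FALSE)
      }))
    } else NULL
    lab_df <- if (is.null(lab_rows)) lab_table()
    else lab_table(lab_rows$item, lab_rows$value, lab_rows$unit,
                   lab_rows$control_value, lab_rows$timestamp)

    record <- patient_record(sprintf("patient-%08d",
                                     as.integer(profile$seed %% 1e8)),
                             index_time, docs, lab_df)

    mention_df <- if (length(mentions)) do.call(rbind, mentions)
    else data.frame(doc_id = character(0), start = integer(0),
                    end = integer(0), cui = character(0),
                    negated = logical(0), doc_type = character(0),
                    offset_days = numeric(0), stringsAsFactors = FALSE)
    gold <- gold_annotations(mention_df$doc_id, mention_df$start,
                             mention_df$end, mention_df$cui,
                             mention_df$negated)

    # Expected verdicts from the full planted-mention table (facts and
    # distractors alike), never from the engine.
    fact_tbl <- data.frame(cui = mention_df$cui,
                           polarity = ifelse(mention_df$negated, "negated",
                                             "affirmed"),
                           doc_type = mention_df$doc_type,
                           offset_days = mention_df$offset_days,
                           stringsAsFactors = FALSE)
    doc_types_present <- vapply(docs, function(d) d$doc_type, character(1))
    expected <- data.frame(
      label = vapply(cl$items, function(it) it$label, character(1)),
      role = vapply(cl$items, function(it) it$role, character(1)),
      status = vapply(cl$items, function(it) {
        c("NOT_MET", "UNKNOWN", "MET")[derive_status(it$expr, fact_tbl, labs,
                                                     doc_types_present) + 1L]
      }, character(1)),
      stringsAsFactors = FALSE)

    structure(list(record = record, lexicon = lex, gold = gold,
                   expected_verdicts = expected, facts = fact_tbl,
                   checklist = cl, profile = profile),
              class = "ground_truth_bundle")
  })
}

#' Challenge-patient profiles
#'
#' Four hard cases patterned on what makes screening difficult in practice:
#' a contraindication buried in an outpatient note, a ratio-to-control lab
#' criterion, a cross-document conjunction (diabetes in one note, prior
#' stroke in another), and mentions present only under negation.
#'
#' @param seed base seed.
#' @return list of four [generation_profile()]s.
#' @export
challenge_profiles <- function(seed = 1L) {
  labs_normal <- list(
    list(item = "Platelets", value = 250000, unit = "per mm3",
         control_value = NA, offset_days = -1),
    list(item = "Glucose", value = 95, unit = "mg/dL", control_value = NA,
         offset_days = -1),
    list(item = "INR", value = 1.1, unit = "", control_value = NA,
         offset_days = -2),
    list(item = "APTT", value = 33, unit = "s", control_value = 30,
         offset_days = -2))
  no_facts <- data.frame(cui = character(0), polarity = character(0),
                         doc_type = character(0), offset_days = numeric(0),
                         stringsAsFactors = FALSE)
  list(
    # 1: anticoagulant use documented only in an outpatient note
    generation_profile(seed + 101L, n_documents = 8L,
                       planted_facts = no_facts, distractor_density = 1,
                       lab_series = labs_normal, bury_in_outpatient = TRUE),
    # 2: ratio-to-control criterion; an older in-range APTT must lose to the
    #    recent elevated one
    generation_profile(seed + 202L, n_documents = 8L,
                       planted_facts = no_facts, distractor_density = 1,
                       lab_series = c(labs_normal[1:3], list(
                         list(item = "APTT", value = 45, unit = "s",
                              control_value = 30, offset_days = -2),
                         list(item = "APTT", value = 31, unit = "s",
                              control_value = 30, offset_days = -10)))),
    # 3: diabetes and prior stroke documented in different departments
    generation_profile(seed + 303L, n_documents = 8L,
                       planted_facts = data.frame(
                         cui = c("C0011849", "C0038454"),
                         polarity = c("affirmed", "affirmed"),
                         doc_type = c("outpatient note", "discharge summary"),
                         offset_days = c(-400, -700),
                         stringsAsFactors = FALSE),
                       distractor_density = 1, lab_series = labs_normal),
    # 4: head injury and internal bleeding mentioned only under negation
    generation_profile(seed + 404L, n_documents = 8L,
                       planted_facts = data.frame(
                         cui = c("C0018674", "C0019080"),
                         polarity = c("negated", "negated"),
                         doc_type = c("admission note", "outpatient note"),
                         offset_days = c(-30, -30),
                         stringsAsFactors = FALSE),
                       distractor_density = 1, lab_series = labs_normal))
}

#' Generate a synthetic cohort
#'
#' `n` independent bundles with per-patient seeds derived from `seed`. With
#' `challenge = TRUE` (and `n >= 4`) the first four patients are the
#' [challenge_profiles()] hard cases.
#'
#' @param n number of patients (>= 1).
#' @param seed cohort seed.
#' @param base_profile optional profile whose fields (other than seed) are
#'   reused for the non-challenge patients.
#' @param challenge include the four challenge patients first.
#' @param cl,lex forwarded to [generate_patient()].
#' @return list of `ground_truth_bundle`s.
#' @export
generate_cohort <- function(n, seed = 1L, base_profile = NULL,
                            challenge = TRUE, cl = demo_checklist(),
                            lex = default_lexicon()) {
  stopifnot(n >= 1L)
  profiles <- list()
  if (challenge && n >= 4L) profiles <- challenge_profiles(seed)
  i <- length(profiles)
  while (length(profiles) < n) {
    i <- i + 1L
    s <- (as.numeric(seed) * 10007 + i * 7919) %% 2147483647
    p <- if (is.null(base_profile)) generation_profile(s)
    else generation_profile(s, n_documents = base_profile$n_documents,
                            doc_type_mix = base_profile$doc_type_mix,
                            planted_facts = base_profile$planted_facts,
                            distractor_density = base_profile$distractor_density,
                            lab_series = base_profile$lab_series,
                            bury_in_outpatient = base_profile$bury_in_outpatient,
                            index_time = base_profile$index_time)
    profiles[[length(profiles) + 1L]] <- p
  }
  lapply(profiles[seq_len(n)], generate_patient, cl = cl, lex = lex)
}

#' Write a ground-truth bundle to disk
#'
#' Emits the standard bundle files plus `lexicon.csv`, `gold.jsonl` and
#' `expected.json` (the expectation file), and the checklist as a rule file.
#'
#' @param bundle a `ground_truth_bundle`.
#' @param dir target directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_bundle(bundle$record, dir)
  write_lexicon(bundle$lexicon, file.path(dir, "lexicon.csv"))
  write_gold(bundle$gold, file.path(dir, "gold.jsonl"))
  writeLines(as.character(jsonlite::toJSON(bundle$expected_verdicts,
                                           dataframe = "rows", pretty = TRUE)),
             file.path(dir, "expected.json"), useBytes = TRUE)
  write_checklist(bundle$checklist, file.path(dir, "checklist.json"))
  invisible(dir)
}
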