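---
title: "Methods: rule-based eligibility screening and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based eligibility screening and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialscreen)
```

## The screening problem and the model

Trial eligibility criteria are a conjunction of heterogeneous conditions:
numeric lab thresholds, narrative findings that must (or must not) appear in
a patient's notes, and temporal qualifiers anchored at an index time such as
emergency-department triage. `trialscreen` models each checklist item as a
rule expression — a finite tree whose leaves are *lab criteria* or *concept
criteria* and whose internal nodes are `AND`, `OR` and `NOT` — and evaluates
it against a patient bundle of timestamped documents and lab results.

A lab criterion compares the **most recent in-window** result for its item
against a threshold. In `RATIO_TO_CONTROL` mode the comparison applies to
`value / control_value`, which is how coagulation criteria of the form
"APTT ≤ 1.4 × control" are expressed; the control denominator is carried on
the lab row itself because it varies by batch. The choice of *most recent*
result when several fall inside the window is a deliberate design decision:
acute screening asks about the patient's current state, and the latest
measurement is the clinical convention. Ties on the timestamp are broken by
input order (last wins), which matters only for feeds that emit corrected
rows after the original.

A concept criterion names one clinical notion as a set of concept unique
identifiers (CUIs) with preferred names, a set of allowed document types,
and an optional window. Multiple concepts inside one criterion are
**disjunctive** — they are a synonym family for one notion (headache *or*
head injury). Conjunctions across notions ("diabetes with prior stroke")
must use an explicit `AND` node. This is an open modelling choice; we chose
disjunction because conjunctive readings are rarer and are expressible with
combinators, while the reverse is not true without inventing nested
criteria.

## Three-valued verdicts

Each criterion evaluates to `MET`, `NOT_MET` or `UNKNOWN`, combined with
strong-Kleene logic (`AND` = `MET` iff all `MET`, `NOT_MET` if any
`NOT_MET`, else `UNKNOWN`; `OR` dual; `NOT` swaps the definite values and
fixes `UNKNOWN`). The third value is reserved for *structural* failure:

* no in-window result for the lab item;
* a ratio-mode result lacking its control value (real lab feeds omit
  controls; this is data absence, not a negative finding);
* no documents of the requested types in the record at all.

Absence of an affirmed mention in an otherwise evaluable record is
`NOT_MET`, not `UNKNOWN` — a checklist answered from records is closed-world
at the leaf. The report layer renders `UNKNOWN` as "no (needs review)"
rather than silently coercing it to "no": treating missing data as a
negative finding is precisely the unsafe shortcut a screening tool must
avoid. Exclusion criteria are *not* inverted by the engine; the verdict
answers the criterion as written and the report displays the role alongside
the status, matching how paper checklists are marked.

Evidence propagates upward from the leaves: a `MET` leaf always carries at
least one lab-row or annotation reference, combinators take the union over
the children whose status contributed, and the union of evidence document
ids forms the report's relevant-document set.

Two known semantic limitations are worth stating. First, a conjunction such
as "diabetes with prior stroke" is evaluated with each conjunct searched
independently across the whole record; the engine does not require both
facts in the same document, nor does it verify a temporal relation between
them. Second, negation context is the only mention context modelled;
hypotheticals and family history are extension points, not features.

## Temporal semantics

Windows are half-open: "within 7 days before index" is
`[index − 7 days, index)` — an event at exactly the window start is inside,
an event at the index time is outside. The symmetric rule applies after the
index. Month and year windows use **calendar arithmetic** (same day-of-month
N months/years earlier, clamped to month end, so Mar 31 − 1 month is
Feb 28/29), not fixed 30/365-day spans: criteria phrased as "within three
months" in protocols refer to calendar dates. All timestamps are ISO-8601
and held in UTC; date-only values mean midnight, which keeps comparisons
deterministic across machines.

## The concept tagger

The tagger is a transparent lexicon matcher rather than a wrapper around an
external concept-mapping engine. The interface is deliberately pluggable —
anything that produces the `annotate_record()` mapping can be substituted —
but the shipped implementation is lexicon-based for two reasons: it is
deterministic and auditable, and practical deployments of dictionary NLP
tools end up enumerating surface forms per concept anyway (the shipped
lexicon's *Anticoagulant* entry, one CUI with warfarin/apixaban/dabigatran/
edoxaban/rivaroxaban as surface forms, is exactly that pattern made
first-class).

Matching is greedy longest-match, left to right, non-overlapping, and
token-boundary aware ("warfarinized" and "forehead" do not match); forms are
case-insensitive unless flagged (acronyms like `ICH` are case-sensitive so
German "ich" or "rich" cannot fire). An ambiguous surface form maps to its
first-declared entry with a warning — word-sense disambiguation is out of
scope, mirroring the known weakness of lightweight concept mappers.

Negation is trigger/scope based: a mention is negated iff a pre-trigger
("no", "denies", "no history of", …) ends within `scope_window` tokens
before it with no terminator between, or a post-trigger ("was ruled out")
starts within the window after it. The default scope is 6 tokens; sentence
punctuation and contrastive conjunctions ("but", "however") terminate
scopes, so "denies headache but reports dizziness" negates only the
headache. Six tokens is the conventional scope length for trigger-based
clinical negation; trigger lists ship as editable data, because nonstandard
negation phrasing is the dominant failure mode of concept extraction in this
domain and sites must be able to extend them without code changes.

## The synthetic-EMR generator and what it does (not) show

Real validation data for this problem cannot be distributed. The generator
emulates the structure of the problem instead: multi-department note streams
per patient (admission, outpatient, discharge, ER, nursing, radiology),
criteria-relevant facts planted affirmatively or under negation inside
boilerplate narrative, distractor mentions of non-criterion concepts, lab
series including ratio-to-control items, and — in the hard cases — critical
contraindications documented *only* in an outpatient note. Expected
verdicts and gold spans are computed **at generation time from the
planted-fact table**, by an independent derivation (a numeric
min/max encoding of the three-valued tables over fact rows), never by
running the engine under test: a test oracle must not share code with the
system it checks.

Defaults that define the study conditions: 10 documents per patient, a mean
of 1.5 distractor mentions per filler note, an 11-item thrombolysis-style
demonstration checklist exercising every rule feature, and cohorts of 50
patients whose first four are the challenge cases (buried contraindication,
ratio lab with a decoy older result, cross-document conjunction,
negated-only mentions). Planted fact offsets are restricted to a safe set at
least a week away from every window boundary of the demonstration checklist,
so the generator's day-based window bookkeeping cannot disagree with the
engine's calendar arithmetic about membership; exact boundary behaviour is
exercised separately by the temporal test suite. All randomness flows from
the profile seed through R's RNG, and the caller's RNG state is restored
afterwards, so identical seeds give byte-identical bundles.

What passing these tests shows: the DSL→rule-file→engine→report chain is
internally consistent, the tagger recovers exactly what a lexicon can
express, negation scoping behaves as specified, and temporal/document-type
filters route evidence correctly. What it does **not** show: performance on
real clinical language — misspellings, ad-hoc abbreviations, section
headers, copy-forward text, non-English fragments — or lexicon coverage of
any actual protocol. Those require site-specific validation against
annotated records, which is why the `validate` subcommand and the gold
annotation format exist.

## Scoring operations

* **Precision/recall/F1 per CUI** against gold spans. Default matching is
  any-overlap of half-open spans with CUI equality (exact-span optional);
  negated predictions are not detections and negated gold entries are not
  expected detections. Zero-denominator precision/recall are reported as
  `NA` ("n/a"), not coerced to 0 or 1.
* **Checklist accuracy**: the mean of per-criterion correctness indicators
  (10 of 11 correct → 0.9091).
* **NASA-TLX**: six 0–20 subscales, weighted by pairwise-comparison counts
  summing to 15, mapped to 0–100 as `(Σ wᵢ rᵢ / 15) × 5`. Because weighting
  elicitation data is often unavailable, an unweighted "raw TLX" fallback is
  provided and flagged in the output.
* **SUS**: standard scoring — odd items contribute `response − 1`, even
  items `5 − response`, sum × 2.5.

## Numerical and degenerate-input choices

Thresholds are compared with exact floating-point comparators; a ratio of
42/30 against an LE threshold of 1.4 is `MET` because both sides compute
the identical double. Rule files are JSON with a declared schema version;
unknown versions **and unknown fields** are rejected rather than ignored —
rule bases are safety artifacts, and silently dropping a field an author
believed was active is worse than failing loudly. An empty checklist is
representable (it screens to an empty verdict list) but flagged by
validation, and a DSL file with no items is a compile error. Serialization
uses full-precision number formatting so `deserialize ∘ serialize` and
`parse ∘ pretty-print` are exact structural identities, properties the test
suite checks over hundreds of randomly generated checklists.

## Problem sizes used in the validation suite

The shipped suite evaluates: 50-patient cohorts for end-to-end
planted-truth recovery (550 criteria per run); 1,000 random
(expression, small-patient) pairs against a brute-force evaluator written
directly from the criterion definitions; 1,000 random cases for the Kleene
algebraic laws; 500 generated checklists for the round-trip laws; and
exhaustive-matcher equivalence for the extraction metrics on instances of up
to 20 annotations. These sizes give dense coverage of the combinatorial
space while keeping a full run comfortably interactive.
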