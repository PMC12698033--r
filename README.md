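# trialscreen

Screening patients for clinical-trial eligibility from electronic medical
records (EMRs) is slow and error-prone: criteria mix numeric lab thresholds
("Platelets <100,000", "APTT ≤ 1.4 × control within 7 days") with findings
that live only in narrative notes ("head injury within three years",
"diabetes with prior stroke"), and the decisive mention is often buried in a
less prominent document such as an outpatient note. `trialscreen` is a
desk-testable R implementation of the computational core of such a screening
tool, for clinical-informatics researchers who want an auditable, rule-based
pipeline they can validate end to end without access to patient data.

The pipeline (each stage is a module with a stable interface):

1. **Rule model** — eligibility checklists as machine-readable rule
   expressions: lab criteria (absolute or ratio-to-control), concept
   criteria (CUI sets over selected document types), calendar temporal
   windows, and `AND`/`OR`/`NOT` combinators. Authored in a small text DSL
   and stored as schema-versioned JSON rule files.
2. **EMR store** — patient bundles: timestamped typed documents (JSONL) plus
   a lab series (CSV) and an index time from which windows are measured.
3. **Concept tagger** — deterministic lexicon-based extraction with UMLS-style
   concept unique identifiers (CUIs): greedy longest match, token-boundary
   aware, semantic-type filtering, and trigger/scope negation detection
   ("no history of …", "denies …"). Broad classes such as *Anticoagulant*
   are one CUI with enumerated drug-name surface forms (warfarin, apixaban,
   dabigatran, edoxaban, rivaroxaban).
4. **Inference engine** — three-valued verdicts per criterion
   (`MET` / `NOT_MET` / `UNKNOWN`) combined with strong-Kleene logic, each
   carrying evidence links to the lab rows and annotation spans that decided
   it. Missing data is `UNKNOWN`, never silently "no".
5. **Reporting** — Markdown/HTML checklist reports with relevant-document
   flags and in-text highlighting of affirmed vs negated mentions.
6. **Metrics** — per-CUI precision/recall/F1 against gold spans, checklist
   accuracy (mean per-criterion correctness), NASA-TLX and SUS scores.
7. **Synthetic EMR generator** — seeded patients with planted facts, gold
   spans and expected verdicts derived at generation time, so the whole
   pipeline is testable against known truth.

For a verdict on criterion \(c\) with children statuses \(s_1..s_k\):
AND is `MET` iff all `MET`, `NOT_MET` if any `NOT_MET`, else `UNKNOWN`; OR is
the dual; NOT swaps `MET`/`NOT_MET` and fixes `UNKNOWN`. A concept criterion
is `MET` iff at least one non-negated annotation with a qualifying CUI lies
in a document of an allowed type whose timestamp falls in the half-open
window `[index − amount, index)`.

## Worked example

```r
library(trialscreen)

cl <- parse_dsl(c(
  'trial "demo"',
  'exclusion "APTT above 1.4x control": lab "APTT" > 1.4 x control within 7 days before index',
  'exclusion "Anticoagulated": concept "warfarin" in [outpatient note] within 6 months before index'
), lexicon = default_lexicon())

idx <- "2024-06-15T00:00:00Z"
record <- patient_record("pt-1", idx,
  documents = list(clinical_document("d1", "outpatient note",
                                     "2024-04-10T09:00:00Z",
                                     "Plan: continue warfarin 3 mg daily.")),
  labs = lab_table("APTT", 45, "s", 30, "2024-06-13T08:00:00Z"))

ann <- annotate_record(record, default_lexicon(),
                       rules = default_negation_rules())
res <- screen_patient(cl, record, ann)
for (v in res$verdicts) cat(sprintf("[%s] %s -- %s\n",
                                    v$status, v$criterion_label,
                                    v$explanation))
```

prints

```
[MET] APTT above 1.4x control -- APTT/control = 1.5 satisfies > 1.4
[MET] Anticoagulated -- 1 affirmed mention(s) of Anticoagulant in qualifying documents
```

The APTT verdict says the most recent in-window result (45 s against a 30 s
control, ratio 1.5) exceeds the 1.4 threshold, so this exclusion criterion
is met; the concept verdict cites the warfarin mention in the outpatient
note, which also places `d1` in the report's relevant-document set.
`render_report(res, record, ann, "out/")` then writes `result.json`,
`report.md` and `report.html`.

A command-line front end covering the same pipeline
(`compile`, `annotate`, `screen`, `validate`, `simulate`) ships at
`inst/cli/trialscreen`.

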