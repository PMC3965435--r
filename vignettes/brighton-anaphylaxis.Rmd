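---
title: "Classifying and screening AEFI reports for anaphylaxis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and screening AEFI reports for anaphylaxis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brightonaefi)
```

## The problem

Passive surveillance systems collect reports of adverse events following
immunization (AEFI) as sets of coded clinical terms plus free text. Two
distinct questions are asked of such corpora. *Diagnosis confirmation*:
does a report satisfy the Brighton Collaboration case definition of
anaphylaxis, and at which level of diagnostic certainty? *Screening*:
which reports should a human expert look at first? These pull in opposite
directions — a case definition is built to be highly specific, a screen
must be highly sensitive — and this package implements both halves
explicitly, so they can be compared on the same corpus.

## Three-valued findings and the closed world

A coded report asserts findings; it almost never asserts their absence.
Whether "skin rash" is missing because the physician saw none, did not
look, or did not record the result is invisible in the data. The package
therefore models every finding status as one of `present`, `absent`,
`unknown`, and evaluates criterion expressions under strong-Kleene
semantics: conjunction is the minimum and disjunction the maximum over
absent < unknown < present, negation reflects the order and fixes
`unknown`, and `at_least(k, ...)` is present when `k` members are
present, absent when more than `length − k` members are absent, and
unknown otherwise. An atom a report does not mention is `unknown` — the
open-world reading — and a criterion that evaluates to `unknown` is *not
satisfied*: applied strictly, an unknown must never confirm a diagnosis.

The alternative reading, that reporters list everything relevant and
omissions mean absence, is made explicit rather than implicit:
`closed_world_complete()` turns every unrecorded catalog atom into an
explicit `absent` finding. It is idempotent, never touches a recorded
status, and is the only place the package converts ignorance into
negative evidence.

## The criteria catalogs

Catalogs are data (YAML under `inst/extdata`), not code, so the clinical
content can be corrected or replaced without reprogramming — the format
deliberately admits other Brighton-style case definitions, though only
anaphylaxis ships. Each catalog lists the atom vocabulary, criteria
(id, organ system, major/minor weight, expression) and level rules over
per-system counts of satisfied criteria. A system's count is the number
of distinct satisfied *criteria*, not atoms. The shipped clinical content
is transcribed from the published case definition of anaphylaxis; it is a
good-faith transcription and should be reviewed against the primary
source before any regulatory use.

Two encodings are shipped, differing in exactly three places:

1. **Negated minors.** The original encoding keeps "X without Y" minor
   criteria literally (`generalized pruritus AND NOT skin rash`;
   `difficulty breathing AND NOT wheeze AND NOT stridor`; the capillary
   refill member of reduced peripheral circulation). Open-world, these
   evaluate `unknown` whenever Y is unrecorded, so they never fire on
   real report data — the motivation for pairing this encoding with
   closed-world completion (`original_closed_world`). The updated
   encoding decomposes them: the positive component X alone carries the
   minor criterion, and the corresponding "X with Y" major still outranks
   it when Y is present.
2. **Compound reporting codes.** Codes like "capillary refill time > 3 s
   without hypotension" are decomposed by the term mapping into one
   present and one absent atom, so a compound annotation and its spelled-
   out equivalent classify identically.
3. **The Level-3 "two other systems" clause.** The clause "≥1 minor
   cardiovascular OR respiratory criterion AND ≥1 minor criterion from
   each of ≥2 different systems" admits two readings. The original
   encoding excludes both cardiovascular and respiratory from the "other
   systems"; the updated encoding excludes only the system supplying the
   qualifying minor criterion. Both are expressible in the level-rule
   algebra (`minor_systems_excluding`), and the fixture
   `level3_interpretation` is the minimal report on which they disagree.

Because the updated criteria are negation-free they are monotone:
promoting any atom to `present` can only raise the outcome. Two useful
consequences are tested as properties: closed-world completion can never
help the updated catalog, and report-by-report the updated open-world
pipeline assigns a level at least as certain as the original
closed-world one.

**Temporal gate.** Sudden onset and rapid progression are necessary
conditions for any positive level in the case definition, and the gate
is therefore applied to all three levels when `require_temporal = TRUE`.
Reporting vocabularies typically cannot encode either, so the default is
the relaxed gate (`FALSE`); the choice is a catalog policy, not a
hard-coded rule.

**The sub-level categories.** A report meeting no level is
`insufficient_evidence` only when it carries an anaphylaxis(-like)
diagnosis code — the category's full name is *reported* anaphylaxis with
insufficient evidence, and treating every unclassified report as such
grossly inflates the category. Which codes count as anaphylaxis-like is
declared in the mapping file (`is_anaphylaxis_diagnosis_term`), not
hard-coded, because the list is open-ended. Below that, `not_a_case`
requires at least one catalog atom present and `no_evidence` none; the
boundary between the two is not defined by the published guideline, and
this operationalization was chosen because it is unambiguous and
testable.

## The screening pipeline

Terms are selected by the uncorrected Pearson chi-square on the 2×2
table of term presence against the expert label, keeping terms with
χ² strictly above the df = 1 critical value at α (3.841 at 0.05). No
Yates correction is applied — the selection rule is a comparison of the
raw statistic against the uncorrected critical value, and the boundary
is strict. Selected terms are unioned with a base SMQ-style list, with
per-term provenance retained.

Reports and the term-set query are tf-idf vectors: tf is binary by
default (coded annotations are sets; a `count` mode exists as a config
switch), idf is ln(N/df) with no smoothing, fitted on the training
corpus; terms unseen in training carry no weight and drop out of the
query. The score is the cosine of the angle between vectors, clamped to
[0, 1]; an all-zero vector scores 0. The default operating threshold is
the Youden-J maximizer on the training ROC — the published operating
point does not name its selection rule, and Youden is the standard
neutral choice. Fitting supports both a full-corpus mode (the primary
analysis) and a random train/test split (default fraction 0.5 when
requested) under which selection, idf and threshold all come from the
training half only.

## Evaluation choices

Sensitivity and specificity intervals are Clopper–Pearson exact binomial
— conservative, and self-describing in the output (`method` column). AUC
is computed by pROC (the standard R implementation, and the one named in
the methodology this package follows); its DeLong confidence interval is
reported, and the test suite cross-checks the AUC against a brute-force
pairwise rank statistic (ties counting one half) to 1e-12. When the
guideline engine is evaluated as a screen, levels 1–3 count as positive
and `insufficient_evidence` counts as negative by default (it flags an
unsupported reported diagnosis, not evidence), with an override.

## The synthetic-data generator

Real benchmark corpora for this task are unavailable: the expert-labeled
report extract is FOIA-restricted and the terminology is licensed. The
generator therefore emulates the *structure* of such a corpus, and its
defaults are fixed study conditions, not tuning knobs:

- `n_reports = 2000`, `prevalence = 0.04` — the scale and case rate of a
  focused post-signal review corpus (a few percent confirmed cases).
- `level_mix = (0.30, 0.68, 0.02)` — the approximate distribution of
  positive classifications over levels 1/2/3 observed in published
  corpus-level counts.
- `p_omit_finding = 0.10` — each planted supporting code is lost with
  10% probability. Omission yields an *unlisted* term (status unknown),
  never an explicit absence, reproducing the reporting defect the
  three-valued model exists for.
- `p_spurious_brighton_term = 0.5` — half of background reports carry
  one or two isolated criterion codes, matching the roughly even split
  between "not a case" and "no evidence" among negatives in published
  counts.
- `p_anaphylaxis_code_given_case = 0.05`,
  `..._given_noncase = 5e-4` — diagnosis codes are rare even among true
  cases (of the order of 12 coded per 236 confirmed in the motivating
  corpus), which is why the engine cannot rely on them.
- Background terms follow a Zipf law (exponent 1) over a synthetic
  800-code vocabulary, ~4 terms per report. The true term-frequency law
  of spontaneous reports is unknown; Zipf is a modeling choice exposed
  in the config.

Positives are planted bottom-up from the *updated* catalog: draw a
level, sample a minimal satisfied-criteria set for that level's rule,
take a minimal supporting atom set per criterion (one disjunct per OR,
k members per at-least), add both temporal atoms, serialize to reporting
codes — routed through compound codes with probability 0.5 where
applicable — then apply omission. Planting through the negation-free
catalog means the same bytes exercise both encodings, and the planted
level is a lower bound on what a noiseless engine must recover (the test
suite asserts exactly that, plus sensitivity 1.0 at zero noise).

What the generator does **not** emulate: free-text narratives, the
hierarchy of a real terminology (synonym preferred terms, term-level
granularity mismatches), correlated comorbidity structure among
background terms, or onset-interval timing beyond the two boolean
temporal atoms. Passing tests on synthetic corpora therefore demonstrate
the logic and the pipeline, not field performance on real reports; the
screening comparisons in particular are directional (expanded SMQ versus
base SMQ on the same seeds), never point estimates of real-world
operating characteristics.

## Numerical and degenerate-input conventions

- Chi-square with a zero marginal (term in all or no reports, or a
  single-class corpus) is defined as 0 and never selected; the cell
  counts are accumulated in doubles to avoid integer overflow.
- A degenerate training ROC (all scores equal) yields no finite Youden
  threshold; the model falls back to 0.5, i.e. calls nothing at typical
  score scales.
- `screen()` calls positive at score ≥ threshold (ties call positive).
- Conflicting assertions on one atom (one code says present, another
  absent) resolve to present and are reported in the corpus diagnostics
  rather than silently resolved.
- All randomness flows from explicit seeds: the generator's seed lives
  in its config, and the command-line interface derives per-stage seeds
  from one global `--seed` by a stable string hash, so adding a stage
  does not shift the streams of the others.

The test suite runs at deliberately modest problem sizes — exhaustive
truth tables over four atoms, corpora of 50–10,000 reports, twenty
paired seeds for the screening-direction property — chosen so the whole
suite completes in a couple of minutes while still exercising every
property at a scale where violations would surface.

## Known limitations

The shipped mapping and base SMQ are synthetic stand-ins; results on
real data require the user's own licensed mapping and term list, and the
published mapping this design follows is itself subjective. The catalog
transcription has not been clinically re-validated. Only the anaphylaxis
case definition ships. Free-text evidence is out of scope by design, and
the screening model's absolute performance on synthetic corpora says
nothing quantitative about real reporting systems.
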