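---
title: "Predicting long hospital stays from structured and unstructured ED data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting long hospital stays from structured and unstructured ED data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edlos)
```

## The problem

When a patient is admitted to a hospital ward through the emergency
department (ED), an early estimate of the total length of stay (LOS) helps
bed management and discharge planning. Most of what is known at that moment
is structured — age, triage codes, a provisional ICD-10 diagnosis — but the
richest description of the patient is the free-text ED note. `edlos`
implements a complete, testable pipeline for asking a precise question: *does
a classifier built from concepts extracted from the ED notes predict a long
stay as well as one built from the structured codes?*

The outcome is binary: a **long stay** is a total LOS (ED time included) of
at least `long_stay_threshold_days` days. The default threshold is 7 days;
with a cohort median just below a week this gives near-balanced classes. A
6-day reading of "longer than the median" is supported through
`srf_params(long_stay_threshold_days = 6)`, but 7 is the default because the
concept-relevance filter below is defined against the 7-day split.

## Concept extraction from ED notes

Extraction is dictionary-based against a hierarchical concept thesaurus
(any TSV of `concept_id`, `parent_id`, `preferred_term`, `synonyms`; the
package ships a synthetic generator and accepts a licensed vocabulary subset
of the same shape). Three steps:

1. **Sub-text splitting** (`split_subtexts()`): sentences are cut on
   terminal punctuation (`. ! ? ;`) and newlines. Clause-level splitting is
   deliberately not attempted; the scope of every later decision is the
   sentence.
2. **Context classification** (`classify_context()`): each sentence gets one
   of four labels — patient/family crossed with affirmation/negation — from
   two independent cue lexicons matched at token boundaries. Neutral text is
   patient-affirmation. The cue inventory is configuration
   (`cue_config()`), with compact English and French defaults; a sentence
   scope with curated cues is a classic, auditable design for clinical
   negation/family detection, and the contract is language-agnostic given
   the lexicons.
3. **Exact most-precise matching** (`match_concepts()`): a concept matches
   when one of its normalized terms occurs as a whole-token sequence in the
   normalized sentence. Normalization is case-folding, accent-folding,
   whitespace collapse — this is what "exact match" means operationally for
   accented clinical text. Longer terms claim their tokens first and
   matched tokens are consumed within a scan ("abdominal pain" blocks a
   second match of "pain" on the same tokens); remaining ties go to the
   earliest start, then the lexicographically smallest concept id, so
   matching is deterministic. The matched set is then reduced by
   `most_precise()`, which removes every proper ancestor of another match.
   A matched concept with no matched descendant is kept as matched, even if
   it is not a leaf: refining it further would invent information the text
   does not contain.

Only sentences labelled **patient-affirmation** contribute to the stay-level
concept set, and only presence is kept (a concept mentioned ten times counts
once). The stay set is the union of the per-sentence reduced sets; we do not
re-reduce across sentences, so adding a sentence can never remove a concept
from a stay — a monotonicity property the tests rely on. A consequence is
that a stay can carry both "pain" and "abdominal pain" if different
sentences support each at their own precision.

## The srf concept filter

Some concepts are so prevalent ("pain" appears in essentially every ED
note) that they cannot separate the classes. For each concept let $a$ and
$c$ be the numbers of long and short **training** stays containing it. The
symmetric relevance frequency is

$$srf = \log_2\!\left(2 + \max\!\left(\frac{a}{\max(1,c)},
\frac{c}{\max(1,a)}\right)\right),$$

and a concept is kept only if $srf$ strictly exceeds the cutoff
$\log_2(2 + (1-p)/p)$ at prevalence threshold $p = 0.45$, i.e. $1.688$; a
concept exactly at the cutoff is non-relevant. Two numerical points worth
making explicit:

* the counts are computed on the training split only. Selecting features
  with test-set outcomes is leakage; the package's tests verify that
  shuffling test labels changes no feature matrix.
* the filter only has power near class balance. If the class split is
  $q : 1-q$, a concept present in *every* stay already scores about
  $\log_2(2 + \max(q,1-q)/\min(q,1-q))$, which exceeds $1.688$ once the
  majority class passes roughly 55%. This is a property of the published
  statistic, not of this implementation, and it is why the default
  generator produces a near-balanced cohort.

## Structured features

* **ICD-10 roll-up** (`rollup_icd10()`): a diagnosis code pooled over fewer
  than five training stays is replaced by its parent (the code minus its
  last character), counts are re-pooled, and the round repeats to a fixed
  point; truncation never goes below three characters. All codes are
  checked against the pooled counts at the start of each round, so two rare
  siblings roll up together instead of one rescuing the other; the
  alternative (sequential, one code at a time) can terminate one level
  higher and was rejected as order-dependent. At transform time an unseen
  code is truncated until it hits a known rolled code, else its one-hot row
  is all zeros.
* **CCMU** (`encode_ccmu()`): digits 1–5 map to themselves, "D" (deceased
  on arrival) to 6 and "P" (psychiatric) to 0. The letter mapping implies a
  numeric reading, so CCMU enters the model as a single ordinal column; a
  one-hot alternative would also be defensible but the mapping's intent is
  plainly ordinal.
* **GEMSA** enters one-hot as an unordered 6-category code.

## Features common to both models

* **Recent prior visit** (`recent_visit_flag()`): 1 iff the patient had an
  ED admission in $[t - 7\,\text{days}, t)$ — half-open, the index instant
  excluded. Both 7-day windows in the package use this convention.
* **Short-term ED activity index** (`activity_index()`): the number of
  cohort ED admissions in the same half-open window, rescaled by linear
  interpolation between the 1st and 9th deciles of those counts and clamped
  to $[0,1]$. Deciles are empirical type-7 quantiles (linear interpolation
  between order statistics). The index uses timestamps only — no outcome —
  so it is computed on the whole cohort. If the two deciles coincide the
  distribution is degenerate and the index is a constant 0.5 with a
  warning. We count ED admissions only: the quantity is an ED crowding
  proxy, and ward-side admissions are not in the stay table's scope.
* Age, gender, zip code, ED LOS and the post-ED ward complete the common
  block. Zip codes rarer than five training occurrences pool into an
  `__other__` bucket — the same rarity rule as the ICD roll-up; unseen
  categories at transform time are all-zero rows.

## Models and evaluation

Both feature sets train a random forest (via `ranger`): classification by
majority vote, Gini importance normalized to sum to one. Prediction ties
(an even vote) are broken under the forest's own stored seed so that
prediction is a pure function of the fitted object — without this, repeated
evaluations of one model can disagree on knife-edge cases.

Tuning (`random_search_cv()`) samples `n_iterations = 50` combinations
uniformly from integer ranges and scores each by mean accuracy over
`n_folds = 3` cross-validation folds. Design choices:

* the fold assignment is drawn once per model run and shared by every
  candidate, and each fold has one forest seed shared across candidates:
  comparisons between candidates are paired, and a degenerate
  single-point space scores identically on every draw;
* ties on the CV score go to the earliest sampled candidate;
* the search bounds default to `n_estimators` ∈ [50, 500],
  `min_samples_split` ∈ [5, 50], `min_samples_leaf` ∈ [1, 20]. The lower
  bound of 5 on `min_samples_split` is a hard invariant — with many
  one-hot diagnosis columns of tiny support, smaller values let single
  stays dictate splits. These ranges are a reconstruction of a sensible
  forest search space and are fully configurable.

`run_comparison()` draws one 80/20 split (training size
`round(0.8 n)`, banker's rounding; simple random by default with an opt-in
stratified mode — with near-balanced classes stratification changes little)
and reuses the *same* partition for both models. It reports the metric
suite (recall, specificity, precision, accuracy, F1, long stays positive),
the per-metric deltas, the prediction concordance with its 2×2 agreement
table, normalized importances and the chosen hyperparameters, plus the
majority-class baseline of the test set. The optional intensive-care
subgroup analysis re-splits and re-tunes within the ICU stays: a subgroup
has its own class balance and feature support, so reusing the full-cohort
models or split would conflate subgroup performance with covariate shift.

Every stage seed derives deterministically from one master seed;
`run_all()` persists each intermediate artifact plus a manifest of MD5
checksums, and two runs with the same configuration are byte-identical.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` draws a latent severity per stay,
$s = 0.3\,z_{\text{age}} + \sqrt{1-0.3^2}\,u$, and routes **all** signal
through it:

* $\log \text{LOS} = \log 5.9 + \beta s + 0.55\,\varepsilon$ with
  $\beta = $ `severity_effect` (default 0.6). Stays with two days or less
  in the post-ED ward are redrawn (the study's inclusion rule), which
  shifts the included-cohort median to about 6.5 days and leaves the 7-day
  classes near balance. At `severity_effect = 0` the outcome is independent
  of every feature — the null cohort used for calibration tests.
* informative concepts (default 12 of 60) appear with probability
  $\text{logit}^{-1}(\alpha_j + 1.2 s)$; $\alpha_j$ carries a
  logistic-normal correction so marginal prevalences still hit their
  targets. One concept is planted near-ubiquitously (98.3% of notes) and
  the mean number of affirmed concepts per note is calibrated to ~17.
* CCMU rises with severity, the intensive-care ward probability follows a
  logistic in severity calibrated to 7.6% prevalence, GEMSA and ED LOS get
  mild severity tilts, and the primary diagnosis is drawn from ~120 sparse
  codes (most frequent ≈ 4%) with a severity-tilted distribution.
* arrivals are uniform over the study window with a mild seasonal
  sinusoid, so the activity index varies; 13% of stays receive a prior ED
  visit within 7 days by re-dating a donor stay onto the same patient.
* notes plant one concept mention per sentence from templates that contain
  no thesaurus terms and no cues; negated and family-context sentences are
  planted at configurable per-mention rates (defaults 0.10 and 0.05) and
  recorded in a ground-truth table, making extraction exactly checkable.

The generator is a test harness, not a language model. Real notes contain
misspellings, abbreviations, clause-level negation scopes, term variants
absent from the dictionary, and concept correlations far richer than one
latent factor. Passing the pipeline's tests therefore demonstrates
correctness of the mechanics (splitting, context labelling, matching,
filtering, encoding, tuning, evaluation) and sane statistical behaviour
(learnable when signal exists, chance-level when it does not) — it does not
certify any particular accuracy on real hospital data, and the headline
numbers of any real deployment must be re-estimated locally.

## Problem sizes and runtime choices

The test suite exercises small cohorts (120–600 stays) for unit and
property checks, and one full-scale run of 5,000 stays with the default
50-iteration, 3-fold search for both models for the learnability check;
the matching null-cohort calibration uses a 15-iteration search, since with
no signal the search has nothing to optimize. The null check accepts an
accuracy within three binomial standard deviations of the majority rate on
the ~1,000-stay test set. Property-style tests run the matcher against a
brute-force oracle on 1,000 generated sentences and the roll-up against a
brute-force fix point on randomized tables.

## Known limitations

* The thesaurus is a single-parent tree; true clinical meta-thesauri are
  multi-hierarchies. Concepts with several parents must be flattened before
  loading.
* Negation/family detection is sentence-scoped and cue-based; it cannot
  resolve "no fever but abdominal pain" into mixed polarities within one
  sentence.
* The srf filter loses selectivity as classes drift from balance (see
  above); with imbalanced cohorts consider re-deriving the prevalence
  threshold.
* `min_samples_split`/`min_samples_leaf` map onto `ranger`'s
  `min.node.size`/`min.bucket`; other forest backends define node limits
  slightly differently, so chosen hyperparameters are not portable across
  implementations.
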