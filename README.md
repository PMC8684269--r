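# edlos

Hospital length-of-stay (LOS) prediction from emergency-department (ED)
data: a tested, reproducible pipeline comparing a classifier built from
**structured** admission data (CCMU/GEMSA triage codes, ICD-10 primary
diagnosis) against one built from **unstructured** data (clinical concepts
extracted from free-text ED notes). It is aimed at health-services and
clinical-informatics researchers who want the full chain — text processing,
feature engineering, model tuning, paired evaluation — as auditable,
seed-reproducible code, exercised end-to-end on a synthetic EHR cohort with
exact ground truth.

## What it implements

* **Concept extraction** from notes against a hierarchical thesaurus:
  sentence splitting, four-way context classification (patient/family ×
  affirmation/negation, cue-based, sentence scope), and exact
  whole-token matching reduced to the **most precise** concepts (an
  ancestor matched alongside its descendant is dropped). Only
  patient-affirmation sentences feed the models; presence is binary.
* **srf concept filter.** For each concept, with *a* and *c* the numbers of
  long and short training stays containing it,

  ```
  srf = log2( 2 + max( a / max(1, c), c / max(1, a) ) )
  ```

  Concepts are kept only if srf strictly exceeds the cutoff implied by the
  45% prevalence threshold, `log2(2 + 55/45) = 1.688`.
* **Feature engineering**: hierarchical ICD-10 roll-up (codes pooled under
  5 stays climb to their parent, re-pooled to a fixed point, never below 3
  characters), CCMU letter mapping (`D -> 6`, `P -> 0`), a recent-prior-visit
  flag (any ED admission in `[t - 7d, t)`), and a short-term ED activity
  index (prior-7-day admission count rescaled between the cohort's 1st and
  9th deciles, clamped to [0, 1]); one-hot assembly of three feature sets
  (common / structured / unstructured) with every data-driven encoding
  fitted on the training split only.
* **Models**: a long stay is a total LOS ≥ 7 days (ED time included).
  Random forests for both feature sets, each tuned independently by a
  50-iteration random search over `n_estimators`, `min_samples_split`
  (lower bound 5) and `min_samples_leaf` with 3-fold cross-validation,
  fitted on a shared 80/20 split and evaluated on the identical test set:
  recall, specificity, precision, accuracy, F1, prediction concordance,
  feature importances, and an optional intensive-care subgroup analysis.
* **Synthetic cohort generator**: deterministic, configurable stays + notes
  + toy thesaurus with a latent severity linking concepts, triage codes and
  diagnoses to LOS, plus per-mention ground truth so extraction is exactly
  checkable. See the vignette (`vignettes/los-pipeline.Rmd`) for what it
  emulates and what it deliberately does not.

## Worked example

```r
library(edlos)

cfg     <- generator_config(n_stays = 1000, seed = 42)
th      <- generate_thesaurus(cfg)
cohort  <- generate_cohort(cfg, th)
concepts <- extract_stay_concepts(cohort$notes, th, default_cues("en"))
res <- run_comparison(cohort$stays, concepts,
                      comparison_config(seed = 1,
                                        space = search_space(n_iterations = 10)))
summary(res)
```

```
Long-stay model comparison (800 train / 200 test stays)
               Structured Unstructured   Diff (pts)
recall              53.2%        57.1%         3.90
specificity         82.9%        78.9%        -4.07
precision           66.1%        62.9%        -3.27
accuracy            71.5%        70.5%        -1.00
f1                  59.0%        59.9%         0.87
Concordance:  79.0%   Majority baseline:  61.5%

Chosen hyperparameters
  structured   n_estimators=182 min_samples_split=7 min_samples_leaf=7 (CV acc 0.689)
  unstructured n_estimators=332 min_samples_split=10 min_samples_leaf=11 (CV acc 0.732)
```

Reading it: both models clear the majority-class baseline (61.5%) by about
ten points on the held-out 200 stays, with accuracies within a point of
each other — the note-derived concepts carry roughly the same long-stay
signal as the triage and diagnosis codes, which is the comparison the
pipeline is built to make. The two models agree on 79% of test stays. Each
model was tuned independently (here with a reduced 10-iteration search for
speed); the importance tables in the full `summary()` output show the
structured model leaning on CCMU while the unstructured model substitutes
severity-linked concepts, with the common features (ED LOS, age, activity
index) prominent in both.

The whole pipeline can also be run as one reproducible unit with artifacts
and an MD5 manifest on disk:

```r
run_all(run_config(seed = 11), out_dir = "run1")
```

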