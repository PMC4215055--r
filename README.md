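# depredict

Predicting a future diagnosis of depression, assessing baseline severity,
and screening for treatment moderators from longitudinal electronic health
record (EHR) data.

Depression is frequently missed in primary care and responds
unpredictably to treatment. This package implements, as a tested R
pipeline, the standard EHR analysis chain for three questions:

* **Will this patient be diagnosed with depression — and how early can we
  tell?** Rule-based phenotyping (ICD-9 code + assertive clinical-note
  term + antidepressant-ingredient mention) defines cases and their
  first-diagnosis *index date*; controls with no depression mention are
  matched 1:6 on exact age and 6-month history-length bin; an
  L1-penalized (LASSO) logistic model over binary code/term indicators,
  binned visit rate and gender is evaluated on histories truncated 0, 6
  and 12 months before the index (the *prediction horizon*).
* **How severe is a treated patient's baseline depression?** Severe
  (PHQ-9 > 19) versus minimal/mild (PHQ-9 ≤ 9) at first treatment, with
  the baseline PHQ-9 score itself excluded as a direct measure of the
  target.
* **Which patients respond to medication vs psychotherapy?** Response =
  a PHQ-9 drop ≥ 5 points after 90 days; per-modality LASSO models, then
  an information-gain screen of the top outcome predictors followed by a
  joint logistic model with feature × treatment interaction terms
  (moderator analysis), Wald p-values raw and Benjamini–Hochberg
  adjusted.

The model at the core is sparse logistic regression: coefficients
minimize the penalized deviance −ℓ(β) + λ‖β‖₁ with λ chosen by 10-fold
cross-validation; discrimination is summarized by the ROC AUC with DeLong
95% confidence intervals. Moderator screening uses the information gain
IG(X;Y) = H(Y) − Σᵥ P(X=v) H(Y|X=v) in bits.

Because the registries behind such analyses are proprietary, the package
ships a seeded synthetic-EHR generator (`simulatePamfPopulation`,
`simulateGhriPopulation`) that reproduces the cohort structure the
pipeline assumes — prodromal signal accumulating before a latent index
date, matched-control strata, PHQ-9 trajectories whose improvement
probability follows a logistic model in baseline severity and modality,
and optional planted moderators — so every stage is testable end to end
with no data access. See the methods vignette
(`vignettes/depredict-methods.Rmd`) for the generator's assumptions and
calibration.

## A worked example

```r
library(depredict)
cfg <- pipelineConfig(seed = 1,
                      pamf = list(nPatients = 7000L),
                      ghri = list(nPatients = 2000L),
                      moderators = list(k = 40L))
res <- runPipeline(cfg, outDir = "results")
```

The written `results/report.md` from this exact run:

```
Cohort: 1000 cases, 6000 matched controls (14.3% depressed)

## Diagnosis AUC by truncation cutoff

| cutoff (days) | AUC | 95% CI |
|---|---|---|
| 0 | 0.936 | 0.919-0.953 |
| -183 | 0.687 | 0.647-0.727 |
| -365 | 0.528 | 0.485-0.572 |

Model size: 415 nonzero coefficients

## Treatment response
- medication: AUC 0.683 (top feature demo:baseline_phq9)
- psychotherapy: AUC 0.663 (top feature demo:baseline_phq9)

## Severity
AUC 0.987 (severe vs minimal/mild)

Significant moderator interactions (BH < 0.05): 0
```

Reading it: the simulated cohort assembles 1000 cases and 6000 exactly
matched controls (14.3% depressed). Diagnosis AUC falls as test histories
are truncated further before the index date — strong at the index, modest
at 6 months, near chance at 12 months, because the generator's 400-day
prodrome leaves only 35 days of signal beyond the one-year cutoff. In
both response models the top-ranked feature is the baseline PHQ-9 score
with a negative coefficient (sicker patients improve less often), the
severity model separates severe from minimal/mild patients without seeing
the score, and no spurious moderator interaction survives BH adjustment
in a world where none was planted.

## Acceptance script

`scripts/acceptance.R` recomputes the headline cohort-composition
quantity from scratch — it simulates a 35 000-patient population with a
5000-case depressed stratum, runs the full phenotyping and 1:6 matching
stages, and reports the depressed percentage of the assembled cohort:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The JSON maps each target id to the recomputed value and the problem size
used. The broader property suite (horizon decay, null calibration,
moderator type-I error and power, baseline-severity dominance, oracle
equivalences, structural invariants) lives in
`tests/testthat/test-acceptance.R`.
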