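---
title: "Methods: phenotyping, horizon prediction and moderator screening for depression EHR data"
author: "depredict maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping, horizon prediction and moderator screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depredict)
```

## The problem

Depression is common, under-diagnosed in primary care, and heterogeneous in
its response to treatment. Longitudinal EHR data — visit streams, ICD-9
diagnosis codes, drug-ingredient mentions and disorder terms extracted from
clinical notes (with negation and family-history annotations), and PHQ-9
severity scores — carry signal about (i) who will be diagnosed with
depression months before the diagnosis is recorded, (ii) how severe a
treated patient's baseline depression is, and (iii) which patients respond
to medication versus psychotherapy. `depredict` implements the full
analysis chain for these three questions as a tested, reusable pipeline:

1. **Terminology**: build a depression term set by expanding a small seed
   set two rounds down an is-a ontology, apply a curation blocklist, and
   derive a depression-specific antidepressant ingredient set from a drug
   indication table (ingredients shared with drugs indicated for other
   conditions are removed).
2. **Phenotyping**: a patient is a depression case iff the record holds a
   depression ICD-9 code, an assertive depression term, and an
   antidepressant-ingredient mention. The index ("first diagnosis") date is
   the later of the first qualifying code and first qualifying drug
   mention; cases need 1.5 years (548 d) of prior visits and at most 100 d
   between first code and first drug mention. Controls have no depression
   code and no depression term mention of any flag state. Each case is
   matched to six controls with identical integer age at index and
   identical 183-day history-length bin, without replacement.
3. **Features**: binary presence indicators per code/term/ingredient over
   the truncated, assertive history; visit rate (visits/day × 365) one-hot
   binned in [0,2), [2,4), …, [18,∞); gender; for treated cohorts also age
   and baseline PHQ-9. Phenotype-defining concepts are excluded and
   logged.
4. **Prediction**: L1-penalized (LASSO) logistic models with the penalty
   chosen by 10-fold cross-validation; ROC/AUC with DeLong 95% intervals;
   a horizon experiment that truncates test histories 0, 6 and 12 months
   before the index date.
5. **Outcomes and moderators**: PHQ-9 severity bins, the ≥5-point
   improvement label, first-treatment episode construction, an
   information-gain screen of outcome predictors, and a joint logistic
   model with feature × treatment interaction terms.

Because the source registries are proprietary, every stage is exercised on
a seeded synthetic generator whose structure mirrors the published cohort
aggregates. The generator is first-class, tested code, not a fixture.

## The synthetic world

### Diagnosis-cohort generator (`simulatePamfPopulation`)

Defaults are pinned to the published aggregates wherever one is printed:
prevalence 1/7 (a 14.3% depressed fraction, assigned by deterministic
stratified rounding), mean record span 8.02 years, visit rate 4.2
visits/patient-year (1.18 M encounters over 35 000 patients), 55.2%
female, ages uniform 18–85. Dates are integer day offsets from a fixed
epoch; visits are homogeneous Poisson with fixed endpoints; background
codes and terms follow a Zipf rank distribution over configurable
vocabularies; note terms are flagged negated with probability 0.10 and
family-history with 0.03.

Each case carries one depression ICD-9 code and one antidepressant mention
separated by at most `caseWindowDays` (60), the later of the two defining
the latent index date, plus one assertive depression term shortly before
the index. The index sits at least 600 days after the first visit (so the
1.5-year history rule is satisfiable) and 7–30 days before the last visit.

**Prodromal signal.** Each of `nSignalFeatures` (120) note terms fires per
visit as a Bernoulli with base probability `signalBaseRate` (0.04); inside
the prodrome window — the `prodromeDays` (400) before the index — the odds
are multiplied by `signalStrength` (4) for cases only. Presence-style
binary features therefore separate cases from controls in proportion to
how much of the window survives truncation, giving an interpretable
AUC-versus-horizon decay.

Three generator choices deserve explanation:

* **Short post-index tail (7–30 d).** No analysis stage uses post-index
  data (training truncates cases at the index). A long post-index tail
  only creates an exposure asymmetry between truncated cases and their
  end-truncated matched controls — cases lose `post` extra days of
  background exposure at every cutoff — which cancels genuine signal with
  an artifact that has no analytic meaning. We keep the tail short.
* **Span dispersion.** Only the mean span (8.02 y) is published. Spans are
  gamma with CV 0.5 (shape 4): wide enough to exercise the history-length
  matching, narrow enough that background feature saturation noise does
  not drown the planted signal the horizon experiment is designed to
  measure.
* **Signal vocabulary (120 features at base rate 0.04).** Calibrated once
  so that the planted AUC-horizon profile qualitatively matches the
  published decay (0.800 at the index, 0.712 at 6 months, 0.701 at 12
  months): with these defaults the synthetic profile is ≈0.93 / 0.69 /
  0.52. The 12-month point is structurally capped in this world: a 400-day
  window minus a 365-day cutoff leaves a 35-day overlap (~0.4 expected
  visits), and an oracle that knows the signal features and conditions on
  exact exposure reaches only ≈0.60. The published feature set has no
  record-length feature to condition on, so roughly 0.52–0.55 is the
  achievable 12-month AUC here; the horizon acceptance check can
  therefore sit within noise of 0.5 at the 1-year cutoff on some seeds.

In matched mode (default) controls are generated in blocks that replicate
each case's exact age-at-index and history-length bin, so 1:6 matching
always succeeds whenever controls/cases ≥ 6 — mirroring a fully matched
published cohort.

### Treated-cohort generator (`simulateGhriPopulation`)

Baseline PHQ-9 scores are drawn from the published severity-bin
proportions (267 / 747 / 1294 / 1652 / 1301; these sum to 5261, not the
stated 5651 — the printed proportions are used and the discrepancy left
as-is), uniform within bins. First treatments are medication, psychotherapy
or both (same-day start) in the printed proportions; records span 2.5
years on average and 70.3% of patients are female.

Improvement — a PHQ-9 drop of at least 5 points at the 90-day score — is
Bernoulli with

P(improve) = logit⁻¹(2.589 − 0.2·baseline + 1.511·medication
[+ γ·moderator·medication]),

where the intercept and medication effect are solved analytically so the
expected improvement rates over the baseline distribution equal the
printed 63.8% (medication) and 36.9% (psychotherapy), and the −0.2/point
slope reproduces the published finding that baseline severity is the
strongest (negative) predictor of response, with synthetic response AUCs
landing near the published 0.661/0.749. The drop magnitude beyond the
5-point threshold is noise and deliberately non-identified. Baselines
below 5 cannot mechanically drop 5 points and are forced non-improved;
this floor is real PHQ-9 arithmetic, so the improvement-versus-severity
curve is zero in the minimal bin and strictly decreasing across the four
bins where improvement is possible.

History features are binary note-term indicators placed strictly before
the 10-day pre-treatment blackout: a Zipf-decaying background vocabulary,
`nSeverityFeatures` whose prevalence rises with baseline severity (what
the severity model can learn once the baseline score itself is excluded),
and an optional planted moderator with a medication-only interaction.

### What a green test does and does not establish

The generator emulates marginal rates, matched structure and planted
effects — not comorbidity correlation structure, bursty utilization,
coding drift, or clinical-text ambiguity. Green tests establish that the
pipeline recovers known structure from data that satisfies its
assumptions; they say nothing about transportability to any real
registry, and the published AUCs are not reproduction targets (they
depend on the proprietary records).

## Numerical and design choices

* **Penalty selection**: 10-fold cross-validation; the 1-SE rule for the
  diagnosis and severity tasks. The response experiments default to
  `lambda.min`: their purpose is ranking predictive features, and at the
  response task's effect size the 1-SE rule often selects the empty
  model, which can rank nothing (response models for cohorts of this
  size are typically reported at 100–200 features). The glmnet path is
  bounded (60 values down to 1% of λ_max); with n > p the default path
  spends most of its time on near-unpenalized fits the selection rules
  never choose.
* **Coefficient ranking**: |β_j|·sd(x_j), so binary indicators and
  wide-range numeric features (age, baseline PHQ-9) compare on one scale.
* **AUC / CI**: trapezoidal AUC (= Mann–Whitney with half-credit ties);
  DeLong variance via midranks; degenerate score vectors give a
  zero-width interval at 0.5. Sensitivity at a requested specificity is
  linearly interpolated on the empirical curve.
* **Truncation conventions**: cutoffs are non-positive day offsets from
  the index; controls (index = end of history) are truncated relative to
  their record end in test sets, while training keeps the published
  asymmetry (cases truncated at index, controls complete). The blackout
  window is half-open, (start−10, start]: the start day itself is
  excluded, day start−10 is kept.
* **Degenerate records**: a single-visit record has span 0; the visit
  rate denominator is floored at one day (rate 365/ y). The 100-day
  code–drug gap is unsigned. Ages derive from birth year only.
* **Expansion rounds**: term-set expansion defaults to two rounds
  (expand, then repeat once with the enlarged set); transitive closure is
  available via `rounds = Inf`. The ontology validity check enforces
  acyclicity by iterative sink stripping.
* **Matching**: without replacement across the entire cohort (control
  reuse would inflate the effective sample); candidate order within a
  stratum is shuffled once per seed, and every shortfall is reported,
  never silently dropped.
* **Moderator screening outcome**: "a change of at least ±5 points" is
  read as |change| ≥ 5 by default, with the one-sided improvement label
  available (`outcome = "improvement"`); both raw Wald and
  Benjamini–Hochberg-adjusted interaction p-values are reported, with
  significance calls defaulting to BH at 0.05 since 100 interactions are
  tested. Interaction estimates flagged by separation (|β| ≥ 15 or
  SE ≥ 100) are reported non-estimable and excluded from the adjustment.
* **Severity encoding in the moderator model**: baseline severity enters
  the candidate set as its standard bin indicators (reference: mild)
  rather than the raw 0–27 score. The minimal bin is a structural zero —
  a 5-point drop is arithmetically impossible below a baseline of 5 — and
  a linear logit forced through those rows attenuates every coefficient
  in the joint model (measured: a planted ln 2 interaction shrinks to
  ≈0.50); the bin dummies absorb the floor and restore the planted
  effect. Age is excluded from the information-gain screen because
  empirical IG over a near-continuous feature is biased upward.

## Known limitations

* The 12-month horizon point of the synthetic world is close to chance by
  construction (see above); with a prodrome window much longer than the
  deepest cutoff the decay profile would hold margin at every horizon.
* The severity-linked history features are conditionally independent given
  the baseline score; real comorbidity structure is richer, so severity
  AUCs on synthetic data run higher than a real registry would give.
* The joint 100-term interaction model assumes enough events per
  parameter; with small cohorts, per-feature models (the documented
  fallback) are more stable.
* Concept identifiers are opaque strings against toy terminology
  fixtures; no live UMLS/RxNorm/Medi-Span resolution is attempted.

## A worked example

```{r example, eval = FALSE}
cfg <- pipelineConfig(seed = 1,
                      pamf = list(nPatients = 7000L),
                      ghri = list(nPatients = 2000L))
res <- runPipeline(cfg, outDir = "results")
res$report$cohort          # 1000 cases, 6000 controls, 14.3% depressed
res$report$diagnosis_auc   # AUC falling with the truncation horizon
res$report$response        # baseline PHQ-9 as the top response feature
```
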