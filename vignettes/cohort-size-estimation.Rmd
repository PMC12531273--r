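---
title: "Estimating cohort size across fragmented clinical databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cohort size across fragmented clinical databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortcapture)
```

## The problem

A hospital's disease cohort is rarely recorded in one place. Diagnostic
billing codes, surgical procedure codes, clinician-curated registries,
patient portals, prescription records, laboratory results, helpline logs,
appointment systems and three kinds of free-text documents (clinic letters,
endoscopy reports, histopathology reports) each flag a partially overlapping
subset of the true cohort. Any single source — even diagnostic codes, often
treated as ground truth — both misses true cases and includes false ones.
`cohortcapture` estimates the total cohort size from such a fragmented
record, treating each database as an imperfect "capture" in a multi-list
capture-recapture design.

Throughout, the absence of a record is encoded as 0, never as missing. This
convention keeps every count, overlap and model well defined; its cost is
that a classifier trained on the flags will under-score patients whose
records genuinely exist but were not captured, which is discussed below.

## The recursive Jaccard protocol

Each database \(B_i\) contributes a flagged set of size \(|B_i|\) and a
precision \(\pi_i\) (the fraction of its flagged patients who truly have the
disease, validated against a chart-reviewed gold standard). The protocol:

1. **Seed.** The primary database (diagnostic codes) seeds the running
   *Combined* union \(C \leftarrow B_1\) and the cumulative estimate
   \(T \leftarrow \operatorname{round}(|B_1|\,\pi_1)\).
2. **Order.** Remaining databases are sorted by precision, descending; ties
   keep their declared order. Integrating high-precision sources first means
   the least reliable databases only ever contribute their (smaller) unique
   remainders.
3. **Step.** For the next database \(B\): the Jaccard index
   \(J(C,B) = |C \cap B| / |C \cup B|\) is recorded (to 3 d.p.); the unique
   contribution is \(u = |B| - |C \cap B|\); the estimate grows by
   \(\operatorname{round}(u\,\pi_B)\) and the union by \(u\).

The union size is a hard upper bound on how many distinct patients were
flagged anywhere; the cumulative total is the cohort estimate. The method's
key assumption — that a database's global precision also holds within its
unique remainder — is generally optimistic, because patients found in only
one database are more often false positives than patients corroborated by
several. The estimate is therefore an **upper** estimate, and the package
pairs it with a classifier-based lower estimate. Two modes are provided:
`set_based` (patient-id sets; intersections computed exactly) and
`summary_replay` (printed flagged/intersection counts, for replaying a
published table). Replay consumes printed intersections rather than
re-deriving them from 3-d.p. Jaccard values, because rounding J reintroduces
±1 errors the printed tables do not contain.

### Numerical conventions

Patient counts are rounded half away from zero; Jaccard indices print at 3
decimal places, half up; percentages at 1 decimal place. These conventions
reproduce published inference tables row for row, and are exposed as
`round_half_away()` / `round_half_up()` so downstream code can match them.
`intersection_from_jaccard()` inverts the Jaccard definition exactly when
given an unrounded index; fed a 3-d.p. index it can be off by one patient,
which is why replay mode prefers printed intersections.

## Sizing the validation cohort

The gold standard must be large enough to support an 11-predictor logistic
model. The Pate–Riley binary-outcome criterion
\[ N = \frac{K}{p(1-p)\,S\,\ln(1-R^2)} \]
is implemented as printed (the log term is negative; the magnitude is taken
and rounded up). With \(K=11\) candidate predictors, prevalence
\(p = 0.165\), shrinkage \(S = 0.9\) and an anticipated Cox–Snell
\(R^2 = 0.05\):

```{r}
riley_min_n(k = 11, p = 0.165, s = 0.9, r2 = 0.05, val_fraction = 0.3)
```

A conservative \(R^2\) of 0.05 reflects the low discriminative value
expected of any single clinical database; shrinkage 0.9 is a standard
allowance. `K` is taken as the plain predictor count — the criterion's
prevalence adjustment already appears in the denominator — which reproduces
the published 1730/519/1211 split.

## The classifier and its calibration

The cohort classifier is an elastic-net logistic regression over the 11
binary database flags (demographics are excluded by name pattern: adding
them does not fix the sampling bias discussed below and worsens
calibration). Defaults: a 50:50 L1/L2 mix; features z-scored with statistics
learned inside each training fold; the penalty weight chosen by the
one-standard-error rule on cross-validated AUC (the most regularized model
within 1 SE of the best), which trades a little apparent fit for fewer
false-positive predictors. Internal validation is nested: a 10-fold inner
loop selects the penalty, a repeated 10-fold outer loop measures held-out
AUROC. The outer loop defaults to 5 repeats — enough to estimate the AUROC
spread on the desk-scale problems the package targets — and accepts 100 for
a full run; the estimator is identical either way. Penalized fitting is
delegated to `glmnet`; fold orchestration, the calibration stack and
everything downstream are implemented here.

Probabilities are recalibrated by Platt scaling — a two-parameter logistic
map fitted to out-of-fold scores only, never training scores — and assessed
three ways: a binned mean-predicted vs observed curve, a loess smooth, and
logistic recalibration (slope/intercept of outcomes on the logit of the
prediction; a calibrated model sits at 1 and 0). Brier scores are reported
before and after scaling. A threshold sweep then converts population scores
into cohort counts: at each threshold, precision/recall/accuracy on the
labeled validation set (percentile bootstrap over patients), the population
count above threshold, and the precision-discounted expected true-positive
total `round(predicted_total × precision)`.

## What the synthetic generator emulates

The generator reproduces the statistical structure the analysis assumes, at
its published scale: a population of 37,947 referrals with 16.5% disease
prevalence; age truncated at 18 with the location parameter solved so the
post-truncation mean hits the configured 51.79 years; sex (60.27% female),
ethnicity (85.04% white) and a gently tilted deprivation-decile distribution
(mean ≈ 5.9) sampled independently per field, since only marginals are
being emulated; referral years uniform on 2007–2023. Eleven database
profiles are calibrated to published operating points: each database covers
a fraction of the population, flags covered diseased patients at its
sensitivity and covered non-diseased patients at a false-positive rate
back-solved from its precision at 75% gold-standard prevalence
(`profile_from_metrics()`). Free-text databases get template documents:
diseased patients receive disease-term or abbreviation documents
(normalized before matching), non-diseased patients receive confounder
colitides ("ischaemic colitis" and friends) at rates concentrated in clinic
letters — which is what drags letter precision below endoscopy precision,
as observed in practice.

The gold standard is sampled only from patients present in **at least two**
databases, stratified to 75% prevalence with a seeded 30% validation split
(2,800 → 840 at the default scale). This deliberately reproduces the
sampling bias of a real chart-review exercise: multi-database patients are
easier to validate. Its downstream consequence — the *edge-node problem* —
is that true positives appearing in a single database receive systematically
lower model probabilities than multi-database true positives, because the
training data contain no single-database examples. The package's tests
reproduce this directionally on synthetic data.

What the generator does **not** emulate: longitudinal visit streams,
correlated demographics, realistic clinical prose, and the unobserved true
generating mechanisms of any real hospital's databases (profiles match
observed operating points, nothing more). Passing tests on this generator
therefore demonstrate that the machinery is correct under the stated
assumptions, not that any particular hospital's numbers will be reproduced.

## Fairness audit

`stratified_auc()` recomputes AUROC within demographic subgroups (sex,
ethnicity, decadal age bands, deprivation quintiles by default; bands are
configurable since published analyses name bands only by example), with
DeLong intervals. Groups below a configurable minimum size (default 30) or
with one outcome class are flagged, never silently dropped. The audit
measures performance gaps; it does not attempt mitigation.

## Degenerate inputs and edge cases

Zero-denominator metrics (e.g. specificity when no true negatives exist)
are reported as 0 with a structured warning, matching how such cells are
printed in validation tables. Empty flagged sets yield Jaccard 0 with a
warning. Zero-variance features survive standardization (scale 1) and are
left for the penalty to zero out. Single-class calibration sets return an
identity Platt map with a warning. Threshold ties resolve to the lowest
candidate. Every stochastic routine takes an explicit seed and is
reproducible byte for byte.

## Desk-scale choices

Unit and property tests run the generator at 2,000–20,000 patients, the
nested CV at up to 2,000 × 11 with one outer repeat, and sign-recovery
simulations at n = 10,000 over 20 seeded replicates; these sizes give the
properties under test comfortable margins while keeping the suite quick.
The pipeline's own defaults remain at the full study scale.

## Known limitations

The protocol's precision-homogeneity assumption is not corrected, only
bounded (upper estimate from the protocol, lower from the
missing-as-0 classifier); log-linear or Bayesian multi-list models are out
of scope. The regex flagger has no negation handling or section awareness
and intentionally over-matches all colitides — maximal recall at the cost
of precision, with the confounder load quantified on synthetic documents.
The combined estimator simply adds the classifier's confident true
positives to the unaccounted-for contribution of databases the model
weights negatively; it inherits both components' assumptions.
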