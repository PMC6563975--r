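---
title: "Validating pneumonia prediction models against an ordinal clinical reference standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating pneumonia prediction models against an ordinal clinical reference standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordival)
```

## The problem this package addresses

Discriminating bacterial pneumonia — which warrants antibiotics — from
viral, self-limiting respiratory infection is one of the hardest calls in
paediatric emergency care. Prediction models for childhood pneumonia were
almost all derived against radiographic pneumonia, but chest x-ray is no
longer considered a valid gold standard, so the models need re-validation
against a *clinically based* diagnosis. That diagnosis is not binary: many
children end the visit aetiologically unresolved. `ordival` therefore
validates models against a five-category ordinal outcome running from
definitely bacterial to definitely viral, measures discrimination with an
ordinal extension of the AUC, and translates model output into the decision
that actually matters at the bedside: can antibiotics be withheld safely
below a risk threshold?

## The ordinal reference standard

Each child is classified in two steps.

1. **Working diagnosis → initial class.** The clinician's end-of-visit
   diagnosis code maps, via a pre-specified table, to `bacterial_syndrome`,
   `viral_syndrome`, or `unknown`. Unmapped codes are a hard error: silent
   dropping would bias the category mixture, so site-specific dialects must
   be made explicit.
2. **Refinement by pathogen identification and CRP.** Detection of a
   bacterial pathogen — alone or as a bacterial/viral co-infection — gives
   category 1 (the treatment consequences are those of a bacterial
   infection); a viral pathogen alone gives category 5. Without pathogen
   identification, syndrome-level codes keep their category (2 or 4)
   regardless of CRP, while `unknown` is resolved by CRP: > 60 mg/L → 2,
   ≤ 60 mg/L → 4 (60 itself on the low side), no CRP measured → 3.

Assumptions worth making explicit: pathogen detection outranks both CRP and
the working diagnosis; "definite" and "probable" are merged within
categories 1 and 5 (pathogen yields in routine care are too low to
subdivide usefully); and refinement uses the *raw* measured CRP — the
225 mg/L truncation is strictly a modelling-input step. The refinement is a
total function over its input lattice, which the test suite verifies by
exhaustive enumeration. The binary endpoint for the harm/benefit analysis
collapses categories 1–2 to "bacterial infection".

## The model zoo

Models are declarative YAML specs, so the validation machinery is data, not
code. Rule models (`rule_any_of`, `rule_tree`) classify high risk when any
predicate fires; predicates support age-gated conditions (nasal flaring
counts only under 12 months). Logistic models compute
inverse-logit(intercept + Σ β·f(x)) with per-term transformations
(`identity`, `log`, `log1p`, `threshold`, `equals`), because the original
publications differ in how they enter CRP and vitals.

Design choices:

- **Coefficients.** The original coefficients of the four logistic models
  are not public in usable form here. The shipped specs carry clearly
  labelled *synthetic placeholder* coefficients with face-valid signs and
  magnitudes, so the pipeline is runnable and testable end-to-end; anyone
  validating real data must substitute the published coefficients. The
  any-of rule model ships only in rule form — its regression coefficients
  were never released by its authors.
- **Oxygen-saturation cutoff.** The single-split decision-tree model is
  printed with both "≤ 92%" and "< 92%" in its source material. The spec
  uses the inclusive form and both cutoff and comparator are ordinary spec
  fields, so the choice is auditable and editable.
- **Tachypnea/tachycardia.** No definition accompanies these predictors in
  the validation literature, so they are derived from respiratory/heart
  rate with age-banded cutoffs (APLS-style: RR ≥ 50/40/30 per min for
  < 12 / 12–59 / ≥ 60 months; HR ≥ 160/150/140/120 for
  < 12 / 12–23 / 24–59 / ≥ 60 months). Recorded binary values always
  override derived ones.
- **Availability gate.** A model is validated only when strictly more than
  50% of its predictors are available (present for at least one record,
  directly or via proxy); exactly half excludes. This keeps hopeless
  validations (a 28-predictor model with half its inputs absent) out of the
  report by design.
- **CRP truncation.** Model inputs cap CRP at 225 mg/L; risk for a child
  with CRP 300 equals risk at 225, which the tests assert.

## Missing data

The pipeline applies, in order: proxy substitution (e.g. retractions for
dyspnoea when dyspnoea is wholly unrecorded — present values are never
overwritten), derivation-population constants for predictors that are
wholly unmeasured (mean imputation; a fractional prevalence constant turns
a binary column numeric, which is exactly what a linear predictor needs),
and multiple imputation for partially missing variables.

The imputer is a fully conditional specification (chained equations): each
partially missing variable is regressed on the other cohort variables;
continuous variables are imputed by predictive-mean matching with a
five-donor pool, binary variables by draws from a logistic model, with five
sweeps by default. A `marginal_hotdeck` method (draws from the observed
marginal) is available as a dependency-light fallback and for stress tests.
One master seed spawns per-imputation substreams, so `m` is reproducibly
extensible and everything is bitwise deterministic given the seed.

Pooling is deliberately simple: the pooled estimate is the arithmetic mean
of the per-imputation statistic, with its SD as the reported spread.
Rubin's variance rules are *not* applied — the quantity pooled here (an
ORC, a count) is reported as mean ± SD across imputations, not with a
confidence interval, and the package does not pretend otherwise.

## The ordinal c-statistic

For score *S* and ordinal outcome category *Y* (1 most bacterial), each
category pair (i < j) contributes a pairwise AUC
A(i,j) = P(S_i > S_j) + ½ P(S_i = S_j), computed exactly via midranks. Two
estimators are exposed because the ORC literature defines variants and the
phrasing "two cases of randomly selected outcome *categories*" does not fix
the weighting:

- `unweighted_pairs` (default): the mean of A(i,j) over observed category
  pairs — every category pair counts equally;
- `pooled_pairs`: the concordant fraction over all cross-category case
  pairs — pairs weighted by n_i·n_j.

Both reduce to the ordinary AUC for two categories, are invariant under
strictly increasing score transforms, and map ORC → 1 − ORC when the
category order is reversed; the tests verify all three properties plus
exact agreement with an exhaustive pair-enumeration oracle at small n.
Binary rule models get an ORC too (high = 1, low = 0, ties ½), but it is
flagged as coarse and their per-category behaviour is reported as a
category × class cross-tabulation instead.

## Threshold harm/benefit analysis

"Low risk" means predicted risk strictly below the threshold (the
comparator is configurable for sensitivity analysis, the strict form is the
default). For each threshold the report gives: the low-risk count, expected
prescriptions (observed minus those withheld in the low-risk group — an
exact accounting identity, tested), and under-treatment (low-risk ∧
bacterial outcome ∧ actually treated). No counterfactual outcome modelling
is attempted: harm is a count of an observable subgroup. Default
thresholds are 10% and 15%; the threshold analysis runs for probability
models whose pooled ORC reaches 0.55, a pragmatic "performs well enough to
bother" criterion, overridable with `force_thresholds`. Percentages round
half away from zero, the convention that reproduces every checkable
printed percentage in the published tables this machinery is modelled on.

## The synthetic cohort generator

`preset("rotterdam_like")` and `preset("coventry_like")` emulate two real
validation populations at the level of *marginal structure*: category
mixtures (7/2/38/24/29% and 12/5/41/24/18%), age and CRP medians/IQRs
(14 months, 16 mg/L vs 19 months, 45 mg/L), CRP measurement rates
(38%/36%), prescription rates (21%/35%), per-variable missingness rates,
and site quirks (several examination findings wholly unrecorded at the
second site; ill appearance essentially absent there).

Modelling choices, declared rather than inferred:

- **Functional forms.** CRP is log-normal per category with the spread
  solved from the target IQR; vitals are truncated normals; age and fever
  duration are log-normals solved from median/IQR. Only medians/IQRs are
  published, so distributional shape is a choice, not an estimate.
- **Category effects.** Each category has a severity score s ∈ {1, ½, 0,
  −½, −1} (bacterial → viral); predictors shift linearly in s on the
  natural scale (log scale for CRP, logit scale for binaries), all scaled
  by a single `effect_size` multiplier. `effect_size = 0` removes every
  category–predictor association (a null construction the tests exploit);
  1 is the default, realistic separation.
- **Correlation.** A single latent severity factor per child loads on the
  vitals, log-CRP and a few findings, since the vitals' mutual
  correlations are unreported. The loading is fixed and documented, not
  fitted.
- **Exact marginal calibration.** The CRP baseline is solved (uniroot on
  the mixture CDF) so the median among *measured* CRP hits the site target
  exactly, and the prescription model's intercept is solved so the expected
  marginal prescription rate equals the site target.
- **Internal consistency.** "Unknown" (category 3) children are generated
  with CRP unmeasured — in the reference standard a measured CRP would
  reclassify them — and the overall CRP measurement target is met by
  scaling the measurement probability in the other categories by
  1/(1 − π₃). Syndrome categories get syndrome-level codes and pathogen
  flags consistent with their category, so the observable classifier
  recovers the latent truth exactly; that recovery is itself a test.

What the generator does **not** emulate: record-level correlation
structure beyond the single factor, MAR/MNAR missingness (MCAR by default;
a category-dependent hook exists for stress tests), seasonal or site
drift, and of course any real child. Passing tests on synthetic cohorts
therefore demonstrate that the *machinery* is correct under the declared
generative model — not that any particular model will discriminate well in
a new real population.

## Numerical conventions and degenerate inputs

Ties in the ORC are handled exactly by midranks (no jitter). An ORC needs
at least two observed categories; a single-category cohort is an error, not
a 0.5. LR+ with specificity 1 returns `Inf` distinctly rather than
erroring, so reports can print it as such. Empty cells and literal `"NA"`
are absent; `0/1/true/false` parse as booleans; unparseable cells become
absent rather than crashing ingestion, but missing mandatory columns and
duplicate ids are hard errors. All randomness (generation, imputation)
flows from explicit integer seeds, and the global RNG state is restored on
exit so library calls do not perturb user sessions.

## Problem sizes used by the shipped checks

The test suite exercises the pipeline at n = 150–500 with m = 1–10
imputations, the generator's marginal checks at n = 10 000, the null-ORC
calibration at 200 seeds × n = 200, and the end-to-end discrimination
benchmark at 20 seeds × n = 500 × m = 10 — sizes chosen to make binomial
3-SE bounds meaningful while keeping a full run in the order of a minute.

## Known limitations

- The shipped logistic coefficients are placeholders; conclusions about
  the *published* models' discrimination require the published
  coefficients.
- Simple mean ± SD pooling understates between-imputation uncertainty
  relative to Rubin's rules; it is the convention the reports use, by
  design.
- The availability gate counts a predictor as available if *any* record
  has it; a predictor present in 1% of records passes the gate and leans
  entirely on imputation.
- No calibration assessment: recalibration-in-the-large leaves
  discrimination unchanged and is out of scope, so predicted risks should
  be read as relative rankings unless the model is known to be calibrated
  for the target population.
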