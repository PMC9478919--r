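---
title: "Discovering blood-count threshold scores in two-arm trials: models and methods"
author: "bctscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering blood-count threshold scores in two-arm trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bctscore)
```

## The problem

Routine complete blood counts are measured on essentially every oncology
patient, repeatedly. Ratios of their components — the
neutrophil-to-lymphocyte ratio (NLR), platelet-to-lymphocyte ratio (PLR),
lymphocyte-to-monocyte ratio (LMR) and neutrophil-to-monocyte ratio (NMR) —
carry information about systemic inflammation and immune competence, and
have repeatedly been associated with outcomes under immune checkpoint
inhibition. A biomarker that is merely *prognostic* (associated with outcome
in every arm of a randomized trial) does not help decide who should receive
the drug; a *predictive* biomarker — one whose association is specific to the
treated arm, i.e. one that modifies the treatment effect — does.

`bctscore` implements, as a tested and reusable pipeline, a discovery
procedure for threshold-based risk scores built from longitudinal blood-count
ratios in a two-arm setting (an immunotherapy arm and a chemotherapy control
arm), together with a synthetic trial generator so that the entire pipeline is
testable without access to restricted patient-level trial data. Counts are
taken at three timepoints: pre-treatment baseline (T1), ~6 weeks on-treatment
(T2, first day of cycle 3) and ~12 weeks on-treatment (T3, first day of
cycle 5).

The pipeline has five stages:

1. **Ratio derivation** (`derive_ratios`) — NLR, PLR, LMR, NMR per patient and
   timepoint; missingness in any component propagates, zero denominators are
   flagged non-evaluable.
2. **Cutoff scans** (`scan_biomarker`, `scan_cutoffs`) — for each biomarker, a
   Cox model of high vs low at each decile cutoff fraction (10%–90%, plus the
   quartiles), per arm, per endpoint (overall survival, progression-free
   survival), univariate and covariate-adjusted.
3. **Screening cascade** (`screening_cascade`) — retain a biomarker iff
   (a) treated-arm significant for *both* OS and PFS in at least a `share` of
   cutoff fractions; (b) *not* control-arm significant under the same rule;
   (c) a ratio, not an absolute count (absolute counts are vulnerable to
   sampling and instrument drift); (d) hazard-ratio direction consistent
   across its significant fractions.
4. **Cutoff narrowing and score building** (`narrow_integer_cutoffs`,
   `enumerate_candidates`, `select_candidate`) — absolute integer cutoff
   candidates from the 25–50% quantile window, a Cartesian grid of
   threshold-combination candidates, and selection by time-dependent AUC
   among candidates significant for OS, PFS, clinical benefit (CB = CR+PR+SD)
   and objective response (ORR = CR+PR) in every cohort.
5. **Evaluation** (`predictive_assessment`, `auc_comparison`,
   `assemble_report`) — within-stratum treatment hazard ratios, a formal
   treatment-by-score interaction test, AUC comparison of the score against
   its single components, Kaplan–Meier summaries.

`bctscore()` runs stages 1–4 end to end and returns a classed fit with
`print`, `summary`, `predict` (risk classification of new patients) and
`plot` methods.

## The statistical core

Every statistical primitive the pipeline relies on is implemented in the
package and verified against independent brute-force oracles in the test
suite; the `survival` package appears only as a cross-check in tests.

**Cox proportional hazards** (`cox_ph`). Newton–Raphson on the partial
log-likelihood with monotone step-halving; the Efron correction for tied
event times is the default (the behavior of standard survival software),
Breslow is available. Convergence is declared when the maximal score
component falls below `1e-8` or the relative log-likelihood change falls
below `1e-10`; the iteration cap is 50. Standard errors come from the inverse
observed information at the maximum and all inference is Wald — hazard ratio
with two-sided 95% CI and p-value — matching the reporting convention of the
clinical literature this pipeline serves. Constant covariates raise an error;
fits whose coefficients run away (|log HR| > 15) or whose information matrix
collapses are flagged as separation and marked non-converged rather than
silently returned. Covariates are centred internally for numerical stability.

**Kaplan–Meier** (`km_fit`). Product-limit estimate with Greenwood variance.
Censorings tied with an event time count as at risk for that event time. The
median is the smallest time at which the curve reaches 0.5, undefined (NA)
when it never does.

**Log-rank** (`logrank_test`). Observed-minus-expected chi-square with
hypergeometric variance, summed over strata when given; with two groups and
no tied event times it equals the squared Cox score test at zero, an identity
the tests assert exactly. Stratification factors are exposed as an argument
and default to none.

**Time-dependent ROC** (`td_auc`). Cumulative-cases / dynamic-controls AUC at
a horizon, with inverse-probability-of-censoring weights from the
Kaplan–Meier estimate of the censoring distribution (events and censorings
swapped); case weights use the left limit G(t−). Marker ties count 1/2, so
with no censoring the estimate reduces exactly to the pairwise Mann–Whitney
AUC and is invariant under strictly monotone marker transforms. The weight
denominator is truncated at `1e-6` to avoid blow-up near the end of
follow-up.

**Relative risk** (`rr_from_table`). Risk ratio from a 2×2 table with the
Katz log-RR normal interval; the p-value is Pearson's chi-square without
continuity correction, switching to Fisher's exact test when any expected
cell is below 5.

**Rank tests** (`rank_test`). A `paired` flag is explicit: paired data get
the Wilcoxon signed-rank test (exact null up to n = 25 without ties),
unpaired data the Mann–Whitney rank-sum test with tie-corrected normal
approximation. The source literature applies a "signed-rank" label to
between-arm comparisons, which are unpaired; the pipeline uses the rank-sum
form between arms and the signed-rank form between timepoints of the same
patients, and the flag makes that divergence explicit rather than silent.

Significance throughout is two-sided p ≤ 0.050, with no multiplicity
correction — deliberately mirroring the practice this pipeline formalizes.
This is a documented caveat, not an endorsement: stage 4's requirement of
significance for four endpoints in every cohort is itself a severe implicit
multiplicity filter, and the null-cohort property test documents that the
probability of any candidate surviving it by chance is small.

## Conventions that matter

Several small conventions change results and are therefore fixed and
documented:

- **Quantiles** are type-7 (linear interpolation), the R default; decile
  cutoffs depend on this.
- **Boundary side**: a value exactly at a cutoff is *high* (`value >=
  cutoff`), chosen so a printed integer cutoff like "NLR at 5" places 5 in
  the high-risk group.
- **Fraction cutoffs** are computed on the treated arm of the panel (the
  combined treated cohort convention).
- **Integer cutoff window**: candidates are the step-multiples inside the
  *closed* quantile window [q25, q50]; the closed upper end keeps a cutoff
  sitting exactly at the median in play. The step is 1, or 10 for
  platelet-ratio-scale markers (median > 50).
- **Landmark convention** (default on): analyses of a timepoint-t biomarker
  include only patients event-free and under follow-up at t, with survival
  measured from t. This guards the immortal-time bias that arises when a
  12-week measurement is correlated with having survived 12 weeks. Trial
  reports usually measure from randomization; both conventions are supported
  (`landmark = FALSE`), and the acceptance script's demonstration run uses
  the from-randomization convention for fidelity to the usual reporting.
- **Score combination rule**: how three thresholds make one high/low call is
  genuinely underdetermined in the source procedure; `any_high` (high iff at
  least one rule fires) is the default because it is the common clinical
  convention for multi-marker risk flags, with `majority`, `all_high` and
  `count_threshold` available. Classification is monotone: raising any ratio
  never moves a patient from high to low.
- **Share parameter**: "significant at all cutoff fractions" is brittle under
  sampling noise; the cascade requires a configurable share (default 0.8) of
  estimable fractions instead. Scan cells with fewer than `min_events`
  (default 10) events in either group are flagged not-estimable and excluded
  from the share.
- **Selection objective**: among candidates significant for all four
  endpoints in all cohorts, maximize the minimum OS AUC across cohorts; ties
  break lexicographically by candidate id, making selection fully
  deterministic.
- **Biomarker families**: different timepoints of the same ratio are strongly
  correlated (within-patient correlation of log-counts across timepoints);
  `bctscore()` keeps at most one timepoint per ratio family when assembling
  the score, ranked by treated-arm scan strength.

The multivariate scans adjust for sex, age, race (white reference,
dummy-coded), ECOG performance status, metastasis and pre-treatment PD-L1
dichotomized at 1% (5% for a cohort labelled BIRCH), complete-case; body-mass
index and smoking are deliberately not modelled.

## The synthetic trial generator

`simulate_cohort(sim_config(...))` generates the world the tests operate in.
Defaults were chosen once, as the package's reference conditions, and
describe a plausible advanced-NSCLC two-arm setting:

- **Cohort structure**: 1,479 treated / 707 control by default, the sizes of
  the combined reference cohorts.
- **Counts** (10^9/L) are log-normal per cell type with locations typical of
  advanced disease — median neutrophils 5.5, lymphocytes 1.05, monocytes 0.7,
  platelets 250 — i.e. neutrophilia with lymphopenia, giving median NLR ≈ 5,
  PLR ≈ 240, NMR ≈ 8, so published integer cutoffs (NLR 5, PLR 180, NMR 6)
  fall inside the 25–50% quantile window the narrowing step searches.
  Within a patient, log-counts are exchangeably correlated 0.7 across
  T1/T2/T3; cell types are independent of each other (a simplification — see
  limitations).
- **Survival**: constant baseline death hazard 0.05/month (median OS ≈ 14
  months) and progression hazard 0.15/month (median PFS ≈ 4.6 months), both
  inflated by `exp(linear predictor)` under proportional hazards and drawn by
  inverse transform. The linear predictor sums *prognostic* effects (both
  arms) and *predictive* effects (treated arm only), each either linear in
  the standardized log-biomarker (log-HR per SD, scale-free) or a *step* at a
  raw-scale threshold (the world in which an integer cutoff is exactly
  right). An arm main effect (`treatment_loghr`) is available so treatment
  benefit or harm can be confined to one risk stratum. Censoring is
  independent exponential (0.02/month) plus administrative at 30 months; PFS
  is the minimum of progression and death under the same censoring, so
  `pfs_time <= os_time` always.
- **Missingness**: counts at T2/T3 are deterministically missing for patients
  whose follow-up ends before the timepoint, plus an independent 5%
  technical-missingness rate. T1 is always present.
- **Response** (CR/PR/SD/PD/NE): the responder probability is logistic in the
  negated survival linear predictor (base 0.22, scale 0.8), and the
  stable-disease probability among non-responders likewise (base 0.30), so
  good-risk patients both respond more and progress less. The bases were
  anchored on the response and clinical-benefit rates printed for the
  reference cohorts (arm-level ORR ≈ 20%, CB ≈ 45%, with risk-group contrasts
  of roughly 17% vs 28% ORR).

What the generator does *not* emulate: between-cell-type correlation
(neutrophils and WBC are independent here, and WBC is not the sum of its
parts), non-proportional or time-varying hazards, per-cycle dosing and dose
delays, covariate-dependent accrual or missingness, and the covariate
distributions of any real trial. Tests passing on this generator therefore
demonstrate the *procedure* — calibration under the null, recovery of planted
structure, determinism — not fidelity to any specific trial's numbers, which
require the restricted patient-level data.

One emergent property of the generator is worth knowing: because different
timepoints of a ratio are correlated and a later-timepoint analysis conditions
on surviving to that timepoint, a baseline (T1) scan of a biomarker whose true
effect sits at T3 can look competitive purely through its larger landmark
population — and a planted step effect depletes high-ratio patients by T3,
shifting the evaluable distribution (and hence the quantile window) downward.
The recovery experiments in the tests plant their effects with this in mind:
the both-arm effect goes on an independent cell type (planting it on PLR leaks
into NLR through the shared lymphocyte denominator and makes NLR genuinely
control-arm prognostic), and the step-recovery experiment plants its cutoff
near the 30th percentile of the *evaluable* population, inside the searched
window.

## Problem sizes used by the tests

The suite runs its recovery experiments at the sizes the procedure is meant
for while staying quick: 20 small fixtures (n ≤ 20) for the Cox-vs-oracle
check; 200 replicates of 200/arm null cohorts for type-I error of the scan;
50 replicates at 750/350 for the cascade recovery; 30 replicates at 1,000
treated for cutoff recovery; 50 replicates at 1,479/707 (the reference
cohort sizes) for the predictive-assessment signature. The acceptance script
re-runs the same experiments from scratch and adds a full three-cohort
discovery run (1,479/707 training, 650 and 430 treated validations).

## Known limitations

- The informal predictive criterion (one stratum's CI excluding 1, the
  other's covering it) is statistically fragile — a significance difference
  is not a significant difference — which is why `predictive_assessment`
  always computes the interaction test alongside it.
- The four-endpoint, all-cohort significance gate in candidate selection is
  strict at realistic validation sizes; when nothing passes, selection
  returns an explicit empty state with the full ranking rather than a forced
  winner.
- Efron's correction is exact only in the no-ties limit; heavy ties with few
  events deserve exact methods the package does not provide.
- No frailty, time-varying coefficients, competing risks or restricted-mean
  survival; the generator's exponential baselines make the proportional
  hazards assumption true by construction, so the pipeline's robustness to
  PH violations is untested here.
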