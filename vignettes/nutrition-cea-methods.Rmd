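---
title: "Methods: simulating and evaluating enteral nutrition-support strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating enteral nutrition-support strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutricea)
```

## Scope and scientific setting

`nutricea` implements the complete computational chain of a three-arm
comparison of enteral nutrition-support strategies — percutaneous
endoscopic gastrostomy (PEG), nasogastric tube feeding (NTF), and oral
nutritional supplements (ONS) — for patients with unresectable esophageal
squamous cell carcinoma treated with concurrent chemoradiotherapy. The
chain has five stages:

1. a seeded synthetic-cohort generator calibrated to the published
   per-arm summary tables (63 subjects per arm),
2. trial statistics: the design-stage sample-size calculation,
   Kaplan–Meier survival, and ANOVA / chi-square group comparisons,
3. three-group propensity-score matching with a caliper on the logit
   scale,
4. a three-state Markov cohort model (disease-free / relapse / death)
   accumulating discounted costs and quality-adjusted life-years (QALYs),
5. cost-effectiveness analysis: the ICER efficiency frontier with
   dominance handling, net monetary benefit (NMB), one-way (tornado)
   sensitivity analysis, and probabilistic sensitivity analysis (PSA)
   with cost-effectiveness acceptability curves (CEACs).

No patient-level data are distributed or required: every downstream stage
is exercised against cohorts produced by the generator, whose targets are
the published group summaries.

## The synthetic-cohort generator

Each arm is described by an `arm_profile`: sample size, weight-change
distribution, nutrition-indicator rates, response probabilities, 1-year
loco-regional progression-free survival (LRFS) and overall survival (OS),
itemised mean costs, hospital days, and baseline covariate distributions.
The shipped configuration (`inst/extdata/default_config.yaml`) carries
the printed values of the source tables: for example weight change
−1.4 ± 4.4 % (PEG), −2.1 ± 3.3 % (NTF), −3.0 ± 5.4 % (ONS), and 1-year
LRFS of 88.3 / 78.6 / 76.8 %.

**Weight change.** The tables report both a continuous summary
(mean ± SD) and a three-way categorisation (gain / unchanged / loss).
We generate hierarchically: a category is drawn from the printed
multinomial, then a continuous percentage from a normal distribution
truncated to that category's band. The bands are gain > +1 %, unchanged
within ±1 %, loss < −1 %; the ±1 % tolerance is a package convention —
the source defines no numeric rule for "unchanged". Using the printed
mean and SD directly as the latent normal parameters would bias the
mixture mean (for the PEG arm, to about −1.7 % instead of −1.4 %),
because the printed category frequencies are not exactly the
normal-implied band probabilities. The constructor therefore solves a
two-parameter moment-matching problem at profile-build time: latent
(μ, σ) such that the category-weighted truncated-normal mixture has
exactly the printed mean and SD. For all three shipped arms the residual
is below 1e-7, so both the continuous moments and the categorical
frequencies converge to their configured values in large cohorts.

**Event times.** The source reports only 1-year survival proportions, so
we adopt the minimal parametric assumption of constant hazards. Death
and loco-regional progression are competing exponentials: the all-cause
death hazard is −log(OS₁yr) and the progression hazard is
−log(LRFS₁yr) + log(OS₁yr), which makes `lrfs_time = min(progression,
death)` reproduce the printed 1-year LRFS and `os_time` the printed
1-year OS (LRFS events include death, hence the validation rule
LRFS₁yr ≤ OS₁yr). Both endpoints are administratively censored at 3
years, matching the study's maximum follow-up of about 32 months. A rate
of exactly 1 gives hazard 0 and a fully censored arm rather than an
error.

**Costs and stay.** Itemised costs and hospital days are gamma with the
printed means and a coefficient of variation of 0.3 — a typical
dispersion for within-protocol healthcare costs; the source reports
means only. Covariates (age, sex, stage, ECOG) are drawn from the
printed baseline distributions; baseline weight is normal truncated to
30–90 kg.

**What the generator does not emulate.** Covariates are mutually
independent and independent of outcomes within an arm; there is no
informative censoring, no toxicity time courses, and the three arms are
drawn as independent samples rather than as overlapping candidate pools.
Consequently, passing tests demonstrate internal consistency of the
pipeline under the published marginals, not covariate-outcome structure
in real data.

**Seeding.** `generate_trial` derives one sub-seed per arm from the
master seed and the arm label (a polynomial string hash folded into the
seed, kept below 2³¹), so an arm's records do not depend on the order in
which profiles are listed, and identical seeds give bit-identical
cohorts.

## Trial statistics

**Sample size.** The design detects a mean weight change of −3 % against
a null of −5 % with SD 5 % (standardised effect 0.4) using a one-sided
one-sample t-test at α = 0.025 and power 0.80. Power is computed exactly
from the noncentral t distribution; `required_sample_size()` searches for
the smallest n reaching the target and returns 52, inflated to 62 by
`planned_enrollment()` at 15 % dropout (⌈n / (1 − d)⌉). The normal
approximation ⌈((z₀.₉₇₅ + z₀.₈)·σ/Δ)²⌉ = 50 is available via
`exact = FALSE` as a cross-check; the exact answer exceeds it by 1–2
subjects, which is precisely why the noncentral-t computation is the
default.

**Survival.** `km_estimate()` wraps the product-limit estimator
(`survival::survfit`), storing only the event times, post-jump survival,
risk sets and event counts; `survival_at()` evaluates the curve as a
right-continuous step function with S(0) = 1. Ties follow the standard
convention: events precede censorings at the same time.

**Group comparisons.** Categorical outcomes use Pearson's chi-square
without continuity correction — on the printed 3×3 weight-category table
this reproduces the published p ≈ 0.001 (8.8 × 10⁻⁴); a corrected
statistic would not. Continuous outcomes use the classical equal-variance
one-way ANOVA. Categories observed zero times everywhere are dropped; a
statistic of exactly zero reports p = 1.

## Three-group propensity matching

The propensity model regresses arm membership on age, sex, stage and
ECOG by multinomial logistic regression (`nnet::multinom`, convergence
tolerance 1e-12). The published procedure matches "on the logit of the
propensity score" with a caliper of 0.6 SD of that logit, but with three
groups the logit is not unique. We use the closest scalar generalisation
of the binary convention: the logit of the *reference-arm* (PEG)
membership probability, with the caliper equal to 0.6 times the SD of
that scalar pooled over all subjects. Whether the original analysis
matched on one logit or several is unknown; this choice is documented,
not inferred.

Matching is greedy 1:1:1 nearest-neighbour without replacement. The
processing order is deterministic: reference subjects are sorted by
their worst-case nearest-candidate distance (computed before any
candidate is consumed), so subjects with scarce candidates match first
and no RNG enters the pass. A triplet is retained only if both
within-triplet distances are inside the caliper; reference subjects that
cannot be matched are counted, never silently dropped. Quasi-separation
(e.g. an ECOG stratum present in only one arm) is handled by capping
coefficient magnitudes at ±15 with a warning, keeping all logits finite;
covariates that are constant in the data are removed with a message,
which also makes the intercept-only limit (identical covariates →
propensity = arm frequencies) exact.

`balance_table()` reports standardized mean differences per covariate
and arm pair before and after matching (categorical covariates as
per-level standardized proportion differences). Two caveats: matching on
a single scalar targets reference-vs-other balance, not every pairwise
contrast; and with only 63 subjects per arm and no donor pool the
attainable balance is limited when the arms genuinely differ at baseline
— the source study drew its comparison arms from larger concurrent
trials. With arms generated from a common covariate distribution the
matched standardized differences shrink to sampling noise (≲ 0.25 at a
few hundred subjects per arm), which is how the balance property is
tested.

## The Markov cohort model

Three states — disease-free, relapse, death — with an annual cycle and
the convention that rewards accrue on state membership at cycle start,
with no half-cycle correction (the convention of the software used by
the source analysis). Cycle t (0-based) contributes occupancy(t) ·
(utilities, state costs) × cycle length, discounted by (1 + r)⁻ᵗ at
r = 3 %/year; the one-time treatment cost enters undiscounted at t = 0.
Utilities are 0.80 (disease-free), 0.53 (relapse), 0 (death).

**Transitions.** `calibrate_annual_probs()` builds the matrix from
follow-up summaries: P(stay disease-free) = LRFS₁yr; death from
disease-free combines the excess mortality 1 − OS₁yr with background
mortality as 1 − (1 − p₁)(1 − p₂), capped at 1 − LRFS₁yr so the row
stays stochastic (the cap binds for the PEG arm, whose 1-year LRFS and
OS nearly coincide); the remainder moves to relapse. From relapse, death
combines the relapse mortality with background; recovery is not
modelled; death is absorbing.

**Defaults where the source's parameter table is unavailable.** The
published model-parameter supplement is not available, so four inputs
are package defaults, chosen once: background mortality 0.01/year (a
plausible all-cause rate for a cohort with median age 62); relapse
mortality 0.5/year, i.e. a median post-relapse survival of about one
year, typical of relapsed unresectable esophageal cancer; and continuing
care costs of $2,000/year disease-free and $5,000/year in relapse. The
disease-free figure is anchored to the published lifetime results
themselves: lifetime cost minus 6-month cost, divided by the implied
life expectancy, is roughly $2,000/year for the PEG strategy. Because
these are calibration choices, the package reproduces the *structure*
of the published cost-effectiveness table (ONS cheapest, PEG most
effective and preferred at realistic thresholds) but its absolute
cost/QALY totals are not claimed as reproductions. Each strategy's
one-time cost is its observed mean total healthcare cost from diagnosis
to 6 months post-treatment ($16,918.55 PEG / $19,123.92 NTF /
$18,399.01 ONS; all costs in USD at 6.37 CNY/USD). Under this
calibration NTF is extendedly dominated on the default frontier, a
sharper verdict than the published sequential frontier — the published
analysis found all three strategies non-dominated.

**Horizon and numerics.** "Lifetime" is operationalised as 38 annual
cycles (median age 62 to age 100), configurable; propagation stops early
once the alive fraction falls below 1e-6. Transition rows must sum to 1
within 1e-9 and the death row must be absorbing; occupancy conservation
and the matrix-power identity are asserted to 1e-9 in the test suite,
and the engine is checked against a 10⁵-path per-individual
microsimulation within three Monte Carlo standard errors.

## Cost-effectiveness analysis

**Frontier.** `icer_frontier()` sorts strategies by cost, removes
strongly dominated ones (no cheaper-and-no-worse competitor), then
iteratively removes extendedly dominated ones until the sequential ICERs
strictly increase. Exact cost-and-QALY ties are broken by label order
and flagged. The frontier is dual to NMB maximisation — a strategy is on
the frontier iff it maximises λ·QALY − cost for some λ ≥ 0 — and the
test suite verifies this equivalence against a brute-force λ-sweep whose
candidate λ set (midpoints between all pairwise slopes) is exhaustive.

**One-way sensitivity.** Parameters are addressed by paths such as
`"PEG/one_time_cost"`, `"*/utilities/1"` or `"NTF/transitions/1/3"`;
each is set to its bounds with everything else at base case and the
pairwise ICER recomputed. A modified transition entry is clamped to
[0, 1] and its row rebalanced proportionally over the remaining entries,
so the matrix stays stochastic. Rows are returned sorted by descending
ICER range (tornado order).

**PSA.** Parameter uncertainty uses method-of-moments distributions:
beta for probabilities and utilities (default relative SD 10 %), gamma
for costs (default 30 %) — the source's actual distributions are
unavailable, so these defaults are explicit and configurable. Each draw
samples every parameter once and applies it to all strategies it targets
(common random numbers), runs each strategy's cohort model, and records
the (cost, QALY) pair; out-of-range transition draws are clamped and
counted. CEACs report the fraction of draws in which each strategy
maximises NMB at each λ on the grid (0 to $50,000 in $5,000 steps by
default); rows sum to 1 by construction. Headline probabilities are read
at $10,000 and $50,000 per QALY, and the preferred strategy at the
$33,962/QALY threshold (three times 2020 per-capita GDP in China). The
published 10,000-draw setting is the default; the test suite uses a few
hundred draws, which is ample for the structural properties it checks
(degeneracy under fixed parameters, seed reproducibility, binomial
convergence).

## Problem sizes used by the tests

Distribution-recovery checks use one 10⁵-subject arm (moments within
three standard errors; categorical goodness-of-fit at α = 0.001; KM at
one year within ±0.005 of the calibrated rates, against a Monte Carlo SE
of about 0.001). The engine-vs-microsimulation check uses 10⁵ simulated
paths; the frontier-vs-oracle check 100 random five-strategy instances;
replicate-mean calibration 1,000 arms of 63 subjects. The full suite
runs in well under a minute on one core.

## Known limitations

* Absolute Markov cost/QALY totals depend on four calibrated defaults
  (state costs, background and relapse mortality); only the published
  table's *printed* values are used for the ICER and NMB checks.
* The matching scalar is one of several defensible three-group
  generalisations; optimal (network-flow) matching and
  inverse-probability weighting are out of scope, as in the source
  analysis.
* The generator produces independent marginals; correlations between
  covariates, outcomes and costs are not modelled.
* Survival p-values comparing arms are not reproduced: the source does
  not name the test behind them, and no log-rank machinery is included.
* No expected-value-of-perfect-information or budget-impact analysis.
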