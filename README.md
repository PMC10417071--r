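# nutricea

Simulation and cost-effectiveness toolkit for three-arm enteral
nutrition-support studies in esophageal cancer treated with concurrent
chemoradiotherapy.

Patients with unresectable esophageal squamous cell carcinoma frequently
cannot maintain oral intake during chemoradiotherapy. Three support
strategies compete in practice — percutaneous endoscopic gastrostomy
(**PEG**), nasogastric tube feeding (**NTF**), and oral nutritional
supplements (**ONS**) — and they differ in nutritional effectiveness,
toxicity, survival and cost. `nutricea` implements, as tested reusable
code, the full analysis chain such a comparison needs:

* **Synthetic cohorts** — seeded patient-level three-arm trials (63
  subjects/arm by default) calibrated so that weight change, nutrition
  indicators, response, 1-year loco-regional progression-free survival
  (LRFS), overall survival (OS), costs and covariates reproduce the
  published per-arm summaries. Event times are competing exponentials
  calibrated to the printed 1-year rates.
* **Trial statistics** — exact noncentral-*t* one-sample sample-size
  calculation, Kaplan–Meier estimation with right-continuous evaluation,
  Pearson chi-square (uncorrected) and one-way ANOVA group comparisons,
  per-arm nutrition/cost summaries.
* **Three-group propensity matching** — multinomial-logistic scores,
  greedy 1:1:1 nearest-neighbour matching on the logit of the
  reference-arm membership probability, caliper 0.6 SD of that logit,
  without replacement; balance diagnostics.
* **Markov cost-effectiveness model** — a 3-state cohort model
  (disease-free / relapse / death), annual cycles over a lifetime
  horizon, utilities 0.80 / 0.53 / 0, costs and QALYs discounted at 3 %
  per year.
* **CEA toolkit** — ICER efficiency frontier with strong and extended
  dominance, net monetary benefit, one-way (tornado) sensitivity,
  probabilistic sensitivity analysis with cost-effectiveness
  acceptability curves.

The central quantity is the incremental cost-effectiveness ratio between
adjacent frontier strategies,

```
ICER(s2 vs s1) = (C2 − C1) / (Q2 − Q1)   [USD per QALY],
```

with strategies ordered by cost, dominated strategies removed, and a
strategy judged cost-effective when its ICER falls below the
willingness-to-pay threshold (three times per-capita GDP, $33,962/QALY,
in the shipped configuration). The dual view `NMB(λ) = λ·Q − C` drives
the acceptability curves.

## Worked example

```r
library(nutricea)

## design-stage sample size: detect −3% mean weight change against a
## null of −5%, SD 5%, one-sided alpha 0.025, power 0.80
required_sample_size(-5, -3, 5)
#> [1] 52
planned_enrollment(52, dropout_rate = 0.15)
#> [1] 62

## a seeded synthetic trial from the shipped three-arm configuration
cohort <- generate_trial(default_arm_profiles(), seed = 1)
nutrition_summary(cohort)[, c("arm_label", "n", "weight_change_mean",
                              "weight_change_sd", "prop_albumin_ge35")]
#>   arm_label  n weight_change_mean weight_change_sd prop_albumin_ge35
#> 1       PEG 63          -1.127146         4.002103         0.9841270
#> 2       NTF 63          -1.955326         3.363615         0.9047619
#> 3       ONS 63          -2.030420         5.327917         0.7936508

compare_groups(cohort, "weight_category", "categorical")
#> Pearson chi-square = 25.13, df = 4, p = 4.734e-05

km <- km_estimate(cohort$lrfs_time[cohort$arm_label == "PEG"],
                  cohort$lrfs_event[cohort$arm_label == "PEG"])
survival_at(km, 1)           # 1-year LRFS in this 63-subject draw
#> [1] 0.9047619

## published cost/QALY table -> sequential ICERs on the frontier
icer_frontier(data.frame(label = c("ONS", "NTF", "PEG"),
                         cost  = c(27753, 28691, 35148),
                         qaly  = c(4.53, 5.06, 6.93)))
#> Cost-effectiveness frontier
#>  label  cost qaly   status    icer
#>    ONS 27753 4.53 frontier      NA
#>    NTF 28691 5.06 frontier 1769.81
#>    PEG 35148 6.93 frontier 3452.94
```

The 63-subject summaries scatter around their calibration targets
(−1.4 ± 4.4 % weight change and 98.4 % normal albumin in the PEG arm;
1-year LRFS 88.3 %) exactly as a 63-patient trial would; large cohorts
recover the targets to Monte Carlo precision. The sequential ICERs of
$1,769.8/QALY (NTF vs ONS) and $3,452.9/QALY (PEG vs NTF) computed from
the rounded published inputs sit within 0.2 % of the published
$1,766.82 and $3,457.65, both far below the $33,962/QALY threshold: the
most effective strategy, PEG, is cost-effective.

The whole chain — generate, analyze, match, model, CEA — runs as one
pipeline with a consolidated JSON report:

```r
report <- run_pipeline(pipeline_config(out_dir = "results/run1", seed = 20180515))
report$cea$preferred_at_threshold
#> [1] "PEG"
```

## Package layout

* `R/` — arm profiles and cohort generation, trial statistics,
  matching, Markov engine, CEA/PSA, pipeline orchestration.
* `inst/extdata/default_config.yaml` — the shipped three-arm study
  configuration (all calibration constants).
* `vignettes/nutrition-cea-methods.Rmd` — model assumptions, calibration
  choices, numerical conventions and limitations.
* `tests/testthat/` — unit, property and acceptance tests with
  independent oracles (closed forms, microsimulation, brute-force
  enumeration).
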