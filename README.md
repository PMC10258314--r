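# oligogrowth

Pretreatment tumor growth rate estimation and survival stratification for
metastatic cancer cohorts.

## What it does, and for whom

Clinical decisions about metastatic disease — in particular whether a
patient with many lesions might still benefit from aggressive local therapy
— usually rest on counting lesions (the oligometastatic convention of ≤5)
or on static baseline burden. This package implements a kinetic
alternative for analysts working with contoured volumetric imaging data:
the **pretreatment tumor growth rate** α (units d⁻¹), estimated per
patient from the cumulative metastatic volume at the last pre-intervention
scan (TP−1) and at treatment baseline (TP0) under the exponential growth
law

    dV/dt = α V        =>        α̂ = ln(V₀ / V₋₁) / Δt

where V is total metastatic volume in cc and Δt the interval in days.
Patients are stratified at the cohort's upper quartile of α̂ into
**slow-paced** (α̂ ≤ threshold) and **fast-paced** (α̂ > threshold) groups,
and overall survival, progression-free survival and second
progression-free survival are compared with Kaplan–Meier curves and
log-rank tests. De novo metastatic patients — no measurable disease at
TP−1 — get the imputation convention of 0.1 cc at −90 days, and a
sensitivity grid re-runs the entire analysis across imputation assumptions
(0.01–1 cc × −150…−30 d). The biomarker is validated against early
volumetric response (Spearman), metastasis count (Spearman) and organ
involvement (Cramér's V). Six alternative growth laws (Mendelsohn,
logistic, linear, surface, Gompertz, von Bertalanffy) are available for
model comparison on richer series.

Because cohorts of this kind are rarely public, the package includes a
seeded synthetic cohort generator (`generate_cohort()`) that emulates the
statistical structure of an 86-patient metastatic melanoma immunotherapy
cohort — volume, count and interval distributions, a growth-rate-linked
survival hazard, censoring, measurement noise — with per-patient ground
truth for recovery testing.

## Worked example

The imputation convention applied to a median-burden patient — 0.1 cc
growing to 28.4 cc in 90 days:

```r
library(oligogrowth)
fit_exponential_two_point(0.1, 28.4, 90)
#> Growth model fit: exponential
#>   parameters: a = 0.0627664
#>   growth rate alpha = 0.0627664 /day (doubling time 11 days)
#>   n_obs = 2, RSS = 0, converged = TRUE
```

An α of 0.063 d⁻¹ means the cumulative volume doubles about every 11 days —
a fast-paced tumor under the usual thresholds.

A full synthetic-cohort analysis:

```r
coh <- generate_cohort(cohort_config(seed = 1))   # 86 patients
fits <- compute_cohort_growth_rates(coh)          # per-patient alpha
strata <- assign_groups(fits$alpha, patient_ids = fits$patient_id)
format(attr(strata, "threshold"), digits = 4)
#> [1] "0.07515"                                   # upper-quartile cutoff, d^-1

rec <- cohort_endpoint(coh, "OS")
slow <- strata$patient_id[strata$group == "slow"]
logrank_test(rec[rec$patient_id %in% slow, ],
             rec[!rec$patient_id %in% slow, ])
#> Two-group log-rank test
#>   n = 64 vs 22; observed events 47 vs 22 (expected 59.25 vs 9.75)
#>   chi-squared = 18.86 on 1 df, p = 1.404e-05
```

The 22 fast-paced patients die at more than twice their expected rate
under the pooled risk set; the slow/fast split separates survival sharply
in this simulated cohort, which carries a log-hazard slope of 15 per unit
α by construction.

The end-to-end pipeline — fits, strata, KM curves, log-rank panel
(overall, oligo/poly subgroups, all quartile pairs), association panel,
waterfall table, sensitivity grid, manifest — writes eight artifacts:

```r
res <- run_analysis(list(output_dir = "out"), cohort = coh)
```

A thin command-line wrapper is installed at
`inst/scripts/oligogrowth.R` (`simulate` and `run` subcommands, YAML
config via `--config`).

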