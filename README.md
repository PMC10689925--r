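# epicourse

Quantitative natural-history analysis for longitudinal epilepsy cohorts
recorded as ordinal monthly seizure-frequency (SF) scores — the data shape
produced by registry and medical-record reconstruction in rare genetic
developmental and epileptic encephalopathies (e.g. *STXBP1*-related
disorders), where clinical-trial readiness requires knowing the epilepsy
course, its predictability, existing treatment response, and the age
windows in which a treatment effect is detectable at all.

Each patient-month carries one score on the six-level SF scale
(0 = no seizures, 1 = monthly, 2 = weekly, 3 = daily, 4 = 2–5/day,
5 = >5/day), overall and optionally per HPO-tagged seizure type. On top of
this the package provides:

* **Cohort model** — long-format CSV I/O, validation, and cohort-median
  imputation of months where seizures were present at unknown frequency
  (`read_cohort()`, `impute_unknown_present()`).
* **Seizure course** — onset and 12-month-remission detection,
  Kaplan–Meier curves with product-limit quantiles, log-rank subgroup
  contrasts, month-wise Wilcoxon comparison of SF distributions
  (`detect_onset()`, `detect_remission()`, `km_fit()`, `logrank()`,
  `monthly_group_comparison()`).
* **Trajectory forecasting** — for every patient with a complete first
  year, the post-first-year course is forecast as the per-month median of
  the k = 10 patients with the most similar first-year histories (mean
  absolute monthly SF difference); a permutation test against uniform
  random trajectories, p = (1 + #{null ≤ observed})/(n_perm + 1),
  classifies "better than chance" forecasting, and the cohort is
  partitioned into high-/low-fidelity subgroups with first-year risk
  features of unpredictability (`forecast_sf()`, `partition_fidelity()`,
  `first_year_risk_features()`).
* **Treatment effectiveness** — patient-month response classes
  (reduced / freedom maintained / unchanged-or-worse), cross-product
  odds ratios with Fisher exact p and Woolf or patient-bootstrap CIs,
  and time-locked percent-reduction curves after treatment initiation
  (`comparative_effectiveness()`, `time_locked_response()`).
* **Virtual clinical trials** — repeated simulated trials (20 sampled
  patients with ongoing seizures, 6/12-month windows, injected 10–50%
  seizure reduction, exact one-sided signed-rank evaluation against the
  same patients' observed histories) summarized as the Observed Frequency
  of Trial Success per start month (`ofts()`, `run_trial()`).
* **Developmental outcomes** — milestone achieved-fractions and
  acquisition-age quantiles, onset–outcome association, and standardized
  score/level summaries by age bin (`achieved_fraction()`,
  `milestone_quantiles()`, `onset_outcome_association()`,
  `score_summary()`).
* **Synthetic cohort generator** — a seeded simulator whose defaults
  encode the cohort structure the analyses assume (≈71% epilepsy, median
  onset 2 months with a neonatal subgroup, variant-class-specific spasm
  and persistence signatures, 12-month remission runs, drugs with known
  injected effects, milestone ages coupled to onset), returning a
  ground-truth record for parameter-recovery testing
  (`generate_cohort()`, `inject_predictability_structure()`).

See the methods vignette (`vignettes/methods.Rmd`) for the model
definitions, parameter meanings, and design rationale.

## Worked example

```r
library(epicourse)

sim    <- generate_cohort(cohort_config(n_patients = 101, seed = 7))
cohort <- impute_unknown_present(sim$cohort)
cohort
#> Seizure-frequency cohort: 101 patients, 10861 seizure rows
#>   epilepsy: 70/101; patient-months observed: 9022
#>   ASM exposures: 156 intervals, 7 drugs
#>   milestones: 808 records
#>   assessments: 127 records

# remission: >= 12 consecutive seizure-free months after onset
rt <- remission_table(cohort)
km_fit(rt$time, rt$event)
#> Kaplan-Meier curve: 66 subjects, 39 events
#>   quantiles (months):  q25= 7, q50=25, q75=not reached, q90=not reached

# forecast the course after the first year from first-year similarity
fc <- forecast_sf(cohort, n_perm = 5000, seed = 8)
fc
#> Seizure trajectory forecast: 101 patients, k = 10, 5,000 perms
#>   better than chance (p < 0.05): 86/101 (85%)
#>   median divergence: 0.100 SF points

# comparative short-term effectiveness from patient-months
comparative_effectiveness(cohort, "phenobarbital", outcome = "short_term")
#> phenobarbital, short_term response: OR 4.38 (95% CI 3.02-6.36), p = 9.08e-13
#>   32 patients, 5754 evaluable patient-months
```

Reading the output: 66 patients had seizure onset and at least a year of
post-onset follow-up; 39 reached remission, half of the risk set by month
25 of life. The forecast beat the uniform-random null for 85% of scored
patients, and the median forecast error was 0.1 SF points per month.
Phenobarbital-exposed patient-months had 4.4-fold higher odds of a
month-over-month seizure reduction than unexposed months — the generator
injected a true SF-halving effect for this drug, and the pipeline
recovers it (the CI is a Woolf interval on patient-months; see the
vignette for the cluster-bootstrap alternative and the confounding
caveats that apply to real cohorts).

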