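---
title: "Quantitative natural-history analysis of seizure-frequency cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative natural-history analysis of seizure-frequency cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicourse)
```

## The data model

`epicourse` analyses longitudinal epilepsy cohorts — typically rare genetic
developmental and epileptic encephalopathies such as *STXBP1*-related
disorders — in which each patient's history is reduced to one ordinal
**seizure-frequency (SF) score per month of life**:

| descriptor | SF |
|---|---|
| no seizures | 0 |
| monthly seizures | 1 |
| weekly seizures | 2 |
| daily seizures | 3 |
| several daily (2–5/day) | 4 |
| multiple daily (>5/day) | 5 |

Months are 1-based; month 1 is the neonatal month, so "neonatal onset"
means first seizures in month 1. Scores exist for the patient overall and
optionally per seizure type (tagged with HPO term identifiers, e.g.
`HP:0012469` for infantile spasms). Treatment exposure is a set of closed
month intervals per drug. Everything is long-format CSV
(`patients.csv`, `seizures.csv`, `asm.csv`, `milestones.csv`,
`assessments.csv`; see `read_cohort()`).

Months where seizures were documented but their frequency was not are
carried as an explicit `present_unknown` marker and resolved by
**cohort-median imputation**: the cell becomes the median SF of that
calendar month of life across donor patients. Donors are by default
patients with a *nonzero* SF that month — the target is known to be
seizing, so seizure-free patients would bias the median toward zero; the
all-patients donor set is available via `donors = "all"` because the
convention is genuinely ambiguous in retrospective registry practice.
Even-count medians are rounded half-up to stay on the ordinal grid, and a
month with no donors falls back to the global nonzero median of the same
series. Imputed cells keep an `imputed` flag; a consistency pass keeps the
overall score at or above the per-type maximum without ever touching a
known cell.

## Onset, remission and subgroup course

Onset is the first month with overall SF > 0. **Remission** is the first
run of at least 12 consecutive seizure-free months after onset; the
reported offset age is the first seizure-free month of that run (the
last-seizure-month anchor is available via `anchor=`, since published
offset ages rarely state which convention they use). A zero run truncated
by the end of observation does not qualify — the patient is censored at
their last observed month. Recurrence after remission is visible in the
run-length bookkeeping but no recurrence survival analysis is offered:
retrospective paediatric cohorts rarely support robust conclusions there.

Onset and remission ages feed standard product-limit machinery
(`km_fit()`, `quantiles()`, `logrank()`, both delegated to the
**survival** package), with the quantile convention "smallest *t* with
S(*t*) ≤ 1 − *q*" and unreached quantiles reported as `NA`. Month-wise
subgroup contrasts (`monthly_group_comparison()`) run a two-sided
Wilcoxon rank-sum test per month of life on the SF distributions of two
patient groups, flag months with fewer than two patients per group as
untested, and report raw p-values by default — the analysis is
descriptive trajectory mapping, not confirmatory testing — with an
optional Benjamini–Hochberg column.

## The forecasting model

The scientific question is whether a child's epilepsy course after
infancy is predictable from infancy alone. For every patient with a
complete first-year history, `forecast_sf()`:

1. computes pairwise **first-year distance** — mean absolute monthly SF
   difference over months 1–12. This is the simplest metric on an ordinal
   scale (L1/12, bounded by 5) and is exactly reproducible; Euclidean and
   rank-correlation alternatives are selectable.
2. predicts each month after month 12 as the **median SF of the k = 10
   nearest patients** observed at that month (rounded half-up; mean
   aggregation optional). Distance ties are broken by patient order after
   a seeded shuffle so the reference set is deterministic under a fixed
   seed. Months with no observed reference are dropped and counted.
3. scores the forecast by its **divergence**: mean absolute difference
   between predicted and observed SF across forecast months.
4. runs a **permutation test of better-than-chance forecasting**: the
   null draws trajectories with SF i.i.d. uniform on {0..5} per month and
   measures their divergence from the observed trajectory;
   p = (1 + #{null ≤ observed}) / (n_perm + 1). The add-one rule keeps
   p strictly positive; the default is 100,000 draws per patient (tests
   use ~2,000 with seeded RNG and Monte-Carlo error bounds). The uniform
   null is a deliberate reading of "randomly generated seizure
   frequencies"; it asks whether the forecast beats an uninformed guess
   on the same scale. A cohort-month resampling null would instead test
   against the cohort's marginal frequency profile; the uniform null is
   the weaker and therefore more conservative claim to advertise.

`partition_fidelity()` then labels a patient **low-fidelity** when the
forecast failed (p ≥ 0.05) *or* the divergence exceeds the cohort's
66.7th percentile of divergence among patients with any seizures. The
percentile is a declared free parameter: published partitions report only
the resulting subgroup sizes, so the threshold was fixed at two-thirds
once and is not tuned. Seizure-free patients whose all-zero trajectories
are predicted exactly have divergence 0 and minimal p, hence are
high-fidelity by construction. `first_year_risk_features()` closes the
loop by asking which first-year features (ongoing seizures at month 12,
offset by month 7, spasms after month 6, long consecutive seizure runs)
are enriched in the low-fidelity subgroup, via Fisher's exact test.

## Treatment effectiveness from patient-months

The unit of analysis is the **patient-month**. Each evaluable month is
classified from its SF transition: `reduced` (SF fell from a nonzero
value), `freedom_maintained` (two consecutive seizure-free months after a
prior seizure history), `unchanged_or_worse` (otherwise, including
seizures reappearing after a free month); pre-onset months are not
evaluable. `comparative_effectiveness()` crosses exposure (drug active
that month; a month under several drugs counts for each, matching
any-ASM practice, with a sole-exposure sensitivity mode) against a
favorable response — `reduced` for short-term effect,
`reduced`/`freedom_maintained` for long-term, `freedom_maintained` alone
for freedom maintenance — and reports the cross-product odds ratio with
a two-sided Fisher exact p. Drugs used by fewer than 10 patients are
refused.

Two known statistical caveats are deliberately surfaced rather than
hidden:

* **Within-patient correlation.** Months of one patient are serially
  dependent, so the default Woolf (log-normal) CI on the 2×2 counts is
  anti-conservative. `ci = "bootstrap"` resamples *patients* with
  replacement and takes percentile bounds; in no-effect simulations the
  cluster bootstrap restores nominal-level coverage where the Woolf
  interval does not.
* **Confounding by treatment era.** Drugs are started when patients are
  seizing, so exposure correlates with disease phase; a drug with no
  pharmacological effect can show an odds ratio far from 1 under
  clinically timed exposure. The package's null-calibration tests
  therefore randomize exposure intervals; real-data estimates should be
  read as associative, not causal.

`time_locked_response()` aligns patients at first initiation and reports
the percent reduction in cohort mean SF relative to the month before
initiation (patients with a zero baseline carry no ratio information and
are excluded with a count), plus the cumulative fraction of spasm
patients whose spasm series has stopped by each month after initiation.

## Virtual clinical trials and OFTS

`ofts()` asks, for every candidate start month: *if a treatment reduced
seizure frequencies by r% over a 6- or 12-month window, how often would a
20-patient trial detect it?* Each simulated trial samples up to 20
patients with ongoing seizures at the start month and full-window
follow-up, scales their observed monthly SF by 1 − r (kept continuous;
an ordinal-rounding mode exists for sensitivity analysis), and compares
treated against observed — the same patients' real histories serve as
the synthetic control — with a one-sided exact Wilcoxon signed-rank test
on per-patient cumulative window SF. The exact null distribution is built
by dynamic programming over sign assignments (`signed_rank_p()`), so tied
cumulative scores are handled without a normal approximation at any n.
The **Observed Frequency of Trial Success** is the proportion of 1,000
seeded trials (200 in tests) reaching p < 0.05; months whose eligible
pool is below 5 are reported as undefined, never zero, and pool sizes are
reported so sparse-window artefacts stay visible.

A consequence of the paired design deserves emphasis: because every
sampled patient's treated series is an exact scaled copy of their
observed series, all paired differences share one sign and the exact p
depends only on the number sampled (p = 2^−n for n patients with any
seizures in the window). The paired OFTS therefore saturates near 1
wherever enough patients are eligible and is exactly 0 at r = 0 — it
measures *recruitability* over the age span. The unpaired option
(`test = "rank_sum"`), which compares the treated distribution against
the observed one across patients, lets between-patient variability drown
small effects and produces the graded success probabilities familiar
from power curves. Both are provided because the underlying
synthetic-control evaluation is described only loosely in the applied
literature; the paired test is the default reading.

## Developmental outcomes

Milestone attainment is summarized as achieved fractions
(`achieved_fraction()`, counts always carried), acquisition-age quantiles
(`milestone_quantiles()`, conditioning on achievers as cumulative-
acquisition figures conventionally do — with a Kaplan–Meier mode treating
non-achievers as censored at last assessment, because achievers-only
conditioning is optimistically biased and users should see both), and
onset–outcome association (`onset_outcome_association()`): Fisher OR for
binary milestones across the neonatal/later onset split, Wilcoxon
rank-sum for ordinal five-level scales (GMFCS-ER, MACS, CFCS), Spearman
correlation with onset age for continuous scores (GMFM-66-IS, PDMS-2) —
Spearman rather than Pearson for robustness on bounded, floor-affected
scores. `score_summary()` bins standardized scores by age and reports
quartiles plus the 90th percentile, or level tallies for classification
scales. `cdc_reference_ages()` ships the CDC 75%-attainment checklist
ages purely as plot annotation.

## The synthetic cohort generator

`generate_cohort()` exists so that every analysis above is testable
without any clinical data. Its defaults *are* the study conditions the
analyses assume:

* 101 patients, epilepsy prevalence 72/101, neonatal onset in 31/72 of
  epileptic patients; non-neonatal onset from a discretized log-normal
  (meanlog = log 2, sdlog = 1.86), chosen so the onset quantiles land
  near 1 / 2 / 7 / ~19 months;
* variant mix 0.53 / 0.44 / 0.03 over PTV-deletion / missense / in-frame
  indel; PTV patients carry an infantile-spasm peak in months 5–6
  (episodic — it rides on top of the baseline course without entering the
  chain state) followed by strongly boosted remission; missense patients
  have suppressed remission in months 10–24 (persistent focal seizures)
  and a higher probability (0.50 vs 0.22) of an intractable,
  rarely-remitting course;
* monthly SF follows a mean-reverting Markov chain on {0..5} drifting
  toward a per-patient active level (2–4), with an absorbing remission
  run entered at a per-month hazard and a small relapse probability after
  a completed 12-month run — the simplest dynamics that expresses both
  long seizure-free runs and refractory variability;
* drugs are assigned with clinically plausible timing (phenobarbital
  near onset, vigabatrin/ACTH in the spasm window, clobazam and the
  ketogenic diet later); a drug's `sf_multiplier` scales the chain's
  drift target while exposed — so the cohort mean SF converges toward
  the multiplied level over ~5 months, and month-over-month reductions
  genuinely become more frequent — and its `freedom` effect multiplies
  the remission hazard and divides the relapse probability;
* milestone ages are log-normal with attainment probabilities and age
  delays coupled to onset stratum (neonatal-onset patients attain motor
  and language milestones at roughly a third of the later-onset rate,
  about the magnitude seen in published cohorts); censoring ages are
  log-normal with median ~6 years, bounded at 6–180 months.

Every latent draw (onset, subgroup, spasm/intractable status, remission
month, per-month applied multiplier, true milestone ages) is returned as
a `ground_truth` record used only by parameter-recovery tests; analysis
functions never see it. `inject_predictability_structure()` overwrites
epileptic patients' courses with a known predictable/unpredictable split
(exact assigned counts, sampled membership) for forecast-recovery
experiments.

What the generator does **not** emulate: dosing and titration, EEG,
genomic background, enrolment logistics, informative dropout, and the
measurement noise of medical-record abstraction. Passing tests on
synthetic cohorts therefore demonstrate that the *machinery* is correct
and recovers known structure — not that any clinical claim transfers to
a particular real cohort.

## Numerical choices and reproducibility

* Ordinal re-gridding always rounds half-up (`0.5 → 1`), never
  half-to-even.
* All randomized procedures (generator, neighbour tie-breaks,
  permutation draws, trial sampling, bootstrap) take explicit seeds and
  restore the caller's RNG state; identical seed means byte-identical
  output.
* Exact small-sample paths: Fisher p by `fisher.test`, signed-rank p by
  the tie-aware DP; the rank-sum test uses R's exact path where sample
  sizes permit and the tie-corrected normal approximation otherwise.
* Degenerate inputs are reported, not silently dropped: constant
  features give `NA` odds ratios with a note, undersized trial pools
  give `NA` OFTS months, milestone quantiles with fewer than five
  achievers are not computed.
* Default problem sizes in the test-suite and acceptance script
  (cohorts of 60–300 patients, 2,000–20,000 permutation draws, 100–200
  trials per month) were chosen as the smallest sizes at which the
  Monte-Carlo error bounds in the tests are comfortably below the
  effects being checked.

## Known limitations

Patient-month effectiveness is associative; no causal adjustment is
attempted. The achievers-only milestone quantiles are biased toward
early attainment (the KM mode quantifies by how much). The forecasting
null is uniform rather than cohort-calibrated, so "better than chance"
is a weak baseline by construction. The paired OFTS measures detectable-
cohort availability rather than statistical power against between-patient
variability — use `test = "rank_sum"` for the latter. And the generator's
subgroup signatures, while shaped to the published natural history of
*STXBP1*-related disorders, are a stylized model: its parameters are
conditions for testing, not estimates.
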