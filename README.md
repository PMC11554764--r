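# mocasim

Cognitive screening tests such as the Montreal Cognitive Assessment
(MoCA, 0–30 points, lower = worse) are routinely "corrected" for age and
education, so that a patient's score is judged against healthy peers of
the same demographics. Because higher age and lower education both lower
test scores *and* raise the probability of cognitive impairment, this
correction has measurable consequences: it changes the test's
discrimination and redistributes sensitivity and specificity across
demographic groups. `mocasim` is a Monte-Carlo simulation pipeline for
quantifying those consequences in a realistic model of the Italian
resident population aged 55–89. It is aimed at biostatisticians and
neuropsychology methods researchers who want to study — or stress-test —
demographic norming of screening instruments.

## The model

A super-population is defined by a 210-cell joint distribution of sex,
five-year age group, completed education (5, 8, 11, 13, or 17 years) and
cognitive status (healthy, MCI, dementia), shipped as a plain-text table.
Each simulated individual gets a continuous age uniform within their age
group and a raw score

```
raw = ŷ(age, edu) − offset(status) + ε,   ε ~ N(0, σ²)
```

where ŷ is a published normative mean-score equation (the default uses a
cubic age term and a log education term), the status offsets are 5.1
points (MCI) and 10.7 points (dementia), and σ = 2.9. The age-education
correction is fitted by OLS on the healthy members of a development
sample (n = 5,000), using the same age/education terms, and applied to
everyone as

```
corrected = raw − ŷ_fit(age, edu) + β₀
```

— rank-equivalent to the usual Z-score correction. Screening cutoffs are
set marginally on the development sample (specificity 97.7% or 84.1%,
or sensitivity 84.1%, as interpolated empirical quantiles), then
discrimination (Mann–Whitney AUC) and sensitivity/specificity — overall
and per age-education stratum — are evaluated on an independent
validation sample (n = 50,000). The experiment is replicated with fresh
cohorts each time; every metric is reported as its mean and 2.5th/97.5th
percentiles across replications.

## Worked example

```r
library(mocasim)
tab <- load_joint_table()
print(tab)
#> Joint sex x age x education x cognitive-status distribution
#>   210 cells; transcribed percentages total 100.004%
#>   marginal prevalence: healthy 86.5%, MCI 9.5%, dementia 4.0%

cfg <- run_config(n_reps = 25, master_seed = 2024)   # defaults otherwise
summ <- run_simulation(cfg)
print(summ)
#> Simulation summary over 25 replications
#>   auc_raw_all        0.9460 [0.943, 0.949]
#>   auc_corrected_all  0.9229 [0.917, 0.927]
#>   auc_raw_mci        0.9246 [0.922, 0.928]
#>   auc_corrected_mci  0.8928 [0.886, 0.898]
#>   auc_diff_all       0.0232 [0.020, 0.028]
#>   auc_diff_mci       0.0318 [0.028, 0.038]
```

Raw scores discriminate impaired (MCI or dementia) from healthy
individuals better than corrected scores (AUC 0.946 vs 0.923); the gap
widens for the harder MCI-vs-healthy contrast (0.925 vs 0.893). At a
fixed marginal operating point the same trade-off appears, and the
stratum table shows why — raw-score performance is wildly heterogeneous
across demographic groups:

```r
cat(sprintf("sensitivity at 84.1%% specificity: raw %.1f%%, corrected %.1f%%\n",
  100 * summary_metric(summ, "se_raw_spec841"),
  100 * summary_metric(summ, "se_corrected_spec841")))
#> sensitivity at 84.1% specificity: raw 84.9%, corrected 77.2%
cat(sprintf("oldest/least-educated stratum, raw: Se %.1f%%, Sp %.1f%%\n",
  100 * summary_metric(summ, "se_raw_spec841_85-89_5"),
  100 * summary_metric(summ, "sp_raw_spec841_85-89_5")))
#> oldest/least-educated stratum, raw: Se 98.5%, Sp 33.5%
```

Corrected scores instead equalize sensitivity and specificity across all
age-education strata (the "equalized odds" fairness criterion), at the
cost of overall discrimination. `write_reports(summ, "outdir")` exports
the AUC, marginal, stratum, and cutoff tables as CSV plus a run
manifest. A command-line wrapper with the same knobs (presets for the
alternative normative equations, rounding/clipping, and the larger
residual SD) lives at `inst/scripts/simulate.R`.

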