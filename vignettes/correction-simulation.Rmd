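---
title: "How age-education correction reshapes screening performance: the simulation model behind mocasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How age-education correction reshapes screening performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mocasim` simulates a population-level cognitive screening programme to
quantify what regression-based age-education correction of MoCA scores
does to discrimination (AUC) and to sensitivity/specificity at fixed
cutoffs, overall and within demographic strata. This vignette explains
the data-generating model, the analysis pipeline, every tunable
parameter, and the numerical and design choices that were genuinely
open.

## The data-generating process

**Population.** The super-population is a joint categorical distribution
over sex (2), five-year age group (7: 55–59 … 85–89), completed
education (5 columns: 5, 8, 11, 13, 17 years, corresponding to 1, 2, 3,
3, 4 completed levels) and cognitive status (healthy, MCI, dementia) —
210 cells, shipped as `inst/extdata/table1_joint_distribution.csv` with
probabilities in percent exactly as printed in the source table (three
decimals), so the fixture stays diff-able. Printed rounding makes the
cells total 100.004%; the loader validates the grid, requires the total
within 0.15 of 100, and rescales so the probabilities sum to exactly 1.
Cohorts are drawn by a single flattened 210-way categorical draw per
individual — distributionally identical to hierarchical sampling and
simpler to test.

**Age within group.** Group "a–b" maps to the half-open real interval
[a, b+1): someone aged 89 years and 11 months is still "89". The
alternative closed convention [a, b] was considered (the choice is
declared, not derivable); it shifts stratum-level raw-score metrics by
only a few tenths of a percentage point, so the half-open reading — the
natural one for completed years of age — is used throughout.

**Scores.** A raw score is the normative mean for a healthy person of
that age and education, minus a status offset, plus i.i.d. Gaussian
noise:

\[ raw = \hat y(age, edu) - \Delta(status) + \varepsilon, \qquad
   \varepsilon \sim N(0, \sigma^2). \]

Four published normative equations are available by name, each written
in centered form \(\beta_0 + \beta_a (t_a(age) - c_a) + \beta_e
(t_e(edu) - c_e)\):

| id | age basis | education basis |
|---|---|---|
| `aiello` (default) | \(age^3\) | \(\ln edu\) |
| `conti` | \(age\) | \(1/edu\) |
| `santangelo` | \(\log_{10}(100-age)\) | \(\sqrt{edu}\) |
| `montemurro` | \(age\) | \(edu\) |

Evaluating an equation at its centering constants returns exactly its
printed intercept, and every equation is strictly decreasing in age and
increasing in education on the supported domain — both are asserted by
the test suite. Whether the Gaussian error is drawn before or after the
offset is subtracted is immaterial (the two formulations are
algebraically identical); the implementation subtracts the offset from
the mean and adds noise once.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `residual_sd` | 2.9 | points | residual SD of the normative fit behind the default equation; 3.4 is the robustness-check alternative (`preset_config("sd34")`) |
| `offset_mci` / `offset_dementia` | 5.1 / 10.7 | points | rounded consensus mean-score deficits of MCI and dementia patients vs demographically matched healthy controls |
| `round_and_clip` | off | — | main analysis keeps scores continuous; the variant rounds to the nearest integer and truncates to [0, 30] (`preset_config("rounded")`) |
| `n_dev` | 5,000 | persons | a very large norming study, representative of the target population |
| `n_val` | 50,000 | persons | large enough that validation noise is small next to development noise |
| `n_reps` | 10,000 | — | full-scale replication count; means stabilize far earlier (see "Problem sizes") |
| `master_seed` | 1 | — | all randomness derives from it |

## The analysis pipeline (one replication)

1. Sample a development cohort (`n_dev`) and an independent validation
   cohort (`n_val`); generate raw scores.
2. Fit OLS of raw score on the *same* transformed age and education
   terms as the generating equation, on healthy development individuals
   only. The basis always matches the generating equation — fitting,
   say, a linear-age correction to cubic-age data would confound
   misspecification with the effect under study.
3. Correct everyone: \(corrected = raw - \hat y_{fit}(age, edu) +
   \beta_0\). Corrected scores are never rounded or clipped. In the
   rounded/clipped variant the regression is fitted on the
   rounded/clipped raw scores — those *are* the observed data — while
   the correction output stays continuous. This correction preserves
   the healthy mean and is an additive shift within each (age,
   education) cell, hence rank-equivalent to a Z-score correction: the
   suite asserts bit-equal AUCs for the two versions.
4. Determine three marginal cutoffs per score type on the development
   sample: the thresholds achieving 97.7% or 84.1% specificity on
   healthy scores (equivalent, under normality, to healthy mean minus 2
   or 1 SD) and 84.1% sensitivity on MCI scores.
5. Evaluate on the validation sample: Mann–Whitney AUC for
   impaired-vs-healthy and for MCI-vs-healthy (dementia excluded), and —
   for MCI-vs-healthy only, the realistic screening contrast —
   sensitivity and specificity at each cutoff, marginally and in each of
   the 35 age-group × education strata.

Replications are aggregated into per-metric means and empirical
2.5th/97.5th percentiles.

## Numerical choices

- **AUC** is computed from midranks, oriented low-score-positive:
  \(P(impaired < healthy) + \tfrac12 P(tie)\). This equals the
  trapezoidal area under the empirical ROC curve; the suite checks it
  against a brute-force all-pairs oracle and against an independent ROC
  implementation, including tied data.
- **Cutoffs** are linearly interpolated empirical quantiles (the "type
  7" rule — the default of mainstream statistical environments):
  deterministic, and achieving the preselected operating point exactly
  up to 1/n for continuous scores.
- **Tie convention:** scores *equal* to a cutoff screen negative
  (positive means strictly below). With continuous scores ties have
  probability zero; the convention only matters for the rounded
  variant, where it is fixed for reproducibility.
- **Rounding** is half-away-from-zero (scores are essentially positive,
  so: half up), because the behaviour at .5 must be deterministic;
  clipping is applied after rounding (immaterial for integer bounds,
  fixed for determinism).
- **Undefined strata:** a stratum with no MCI (or no healthy) members
  in a replication has undefined sensitivity (specificity); it is
  recorded as missing and dropped from that metric's aggregation, never
  counted as zero. The marginal metrics are exact count-weighted
  averages of the defined stratum metrics — an identity the suite
  asserts to 1e-12.
- **Seeding:** replication *i* uses seed `(master_seed + i) mod
  (2^31 - 1)`, so any replication can be reproduced in isolation and
  the summary is a pure function of configuration and master seed.
- **Degenerate inputs:** malformed population tables (wrong cell count,
  negative probabilities, totals far from 100%, inconsistent education
  level mapping) are rejected at load with the offending row named;
  rank-deficient correction designs, empty AUC classes, and cohorts
  lacking a status class raise errors rather than silent NaNs.

## What the generator emulates — and what it does not

The generator reproduces the *stated* population model: exact cell
probabilities, uniform within-group ages, equation-based means,
homoscedastic Gaussian residuals, and exact status offsets. Real data
differ in ways this model deliberately ignores: residuals of a bounded
integer test are neither Gaussian nor homoscedastic (ceiling effects
compress variance at high scores); status offsets vary across studies,
languages, and disease severity; prevalence inputs are extrapolated
from older regional data; and norming samples are rarely representative
of their target population. Passing tests therefore demonstrate a
faithful implementation of this model, not transportability of the
numeric results to any particular clinic.

## Problem sizes

Statistical behaviour is verified at desk scale: the packaged
acceptance tests use 200 replications per configuration and the
reproduction script (`scripts/acceptance.R`) uses 500, both at the full
n_dev = 5,000 / n_val = 50,000. Per-replication 95% spreads are about
±0.003 for AUC and ±2–4 percentage points for the operating-point
metrics, so the Monte-Carlo standard error of a 200-replication mean is
an order of magnitude below the comparison tolerances; the full 10,000
replications change the percentile estimates, not the means, and remain
a configuration choice (`run_config(n_reps = 10000)`).

## Known limitations

- Sex affects sampling (via the joint table) but not scores: none of
  the four normative equations, as used here, includes a sex term.
- Only the three cutoff strategies above are implemented; predictive
  values (PPV/NPV), partial AUC, per-replication confidence intervals,
  and publication-grade figures are out of scope (the stratum CSV
  export carries all per-stratum means needed to draw them).
- The sparsest stratum (youngest, most educated, ≈15 MCI cases per
  50,000-person validation sample) has noisy per-replication
  sensitivity; its replication mean is stable but remains the quantity
  most sensitive to threshold-selection minutiae.
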