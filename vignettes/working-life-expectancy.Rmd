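---
title: "Working life expectancy from annual register data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working life expectancy from annual register data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

```{r}
library(worklife)
```

## Overview

`worklife` estimates *working life expectancy* (WLE) — the number of years a
person can expect to spend employed from a given age onward — and its
companions (years unemployed, inactive, retired, and total remaining life)
from annual labor-market register data. Two estimators are implemented and
compared:

* an **incidence-based** estimator: a discrete-time Markov chain multistate
  life table built from estimated one-year transition probabilities, and
* a **prevalence-based** estimator: Sullivan's method, which weights an
  ordinary period life table by cross-sectional state prevalences.

The package ships a seeded synthetic register generator with a known
ground-truth transition regime, so every stage of the pipeline — ingestion,
estimation, mortality alignment, life-table construction, decomposition, and
the Markov/Sullivan comparison — can be validated against analytic answers
without access to confidential register data.

## The state space and the annual panel

Four living states plus death:

* `employed`, `unemployed`, `inactive`, `retired`, and absorbing `dead`;
* ages 15–99 (single years), calendar years 2004–2013, so transitions are
  observed for the nine periods 2004/05, …, 2012/13.

Register extracts arrive as *spells* (person, start/end dates, state,
occupation). `assign_annual_states()` collapses them to one state per person
and year by **dominant state**: the state occupied the most months of the
year, with ties broken in the order employed > unemployed > retired >
inactive. Three recodes keep the panel consistent with institutional reality:

* at ages 65 and above, unemployment and inactivity are recoded to
  `retired`;
* at ages 80 and above, everyone alive is `retired`;
* a person absent from the register in a year, aged under 65, is `inactive`.

Occupational class uses the **highest category ever attained** (a running
maximum over the total order unskilled manual < unskilled non-manual <
skilled manual < skilled non-manual), so a person's class never falls during
an unemployment or inactivity spell.

`build_person_years()` and `build_transition_records()` turn the annual
panel into exposure and origin–destination records; deaths enter as
transitions into `dead` dated to the year after last exposure. No
transitions are formed out of the final observed year.

## Estimating transition probabilities

`fit_transition_models()` fits **ten separate multinomial logistic
regressions** (`nnet::multinom` on aggregated counts), one per sex × age
band, with bands 15–29, 30–54, 55–64, 65–79, 80–99. Splitting by band keeps
each fit small and lets age effects differ by life-course phase. Within each
fit, the linear predictor for destination (relative to staying) contains:

* origin state,
* a cubic regression spline in age, `splines::bs(age, df = 8)`, with
  boundary knots pinned to the band's age range so that predictions over the
  full band never extrapolate beyond the knots,
* calendar-year indicators relative to the first year (no indicator for the
  final year, which contributes no transitions),
* when occupation is used: occupational class main effects and their
  interaction with year.

A tiny ridge penalty (`decay = 1e-6`) stabilizes separation in sparse cells.
`predict_probability_set()` evaluates the fitted models on the complete
grid (sex × occupation × year × age × origin × destination) and then
enforces the structural boundary rules exactly: destination ages 65+ move
unemployed/inactive mass to retired, destination ages 80+ move all non-death
mass to retired, and age 99 is certain death; rows are renormalized so each
origin row sums to one. `glance()` and `tidy()` expose per-fit summaries and
coefficients; degenerate subsamples (a single observed destination) fall
back to the deterministic prediction with a warning.

The empirical analogue, `empirical_probability_set()`, computes raw
frequencies and is used both as a cross-check on the models in well-exposed
cells and as a nonparametric alternative.

## Aligning mortality to a reference life table

Register-implied death probabilities are noisy and can be biased (e.g., by
unregistered emigration). `adjust_probability_set()` therefore rescales the
state-specific death probabilities within each (sex, occupation, year)
stratum so that the **occupancy-weighted aggregate** death probability at
each age matches a reference period life table for that sex:

1. compute the stratum's conditional-on-survival destination distribution
   once — it is held fixed throughout;
2. iteratively scale the state-specific death probabilities so that the
   occupancy-weighted q̂ₓ equals the reference qₓ (tolerance 1e-6, at most
   50 iterations), capping individual probabilities at 1 and reporting any
   capped cells;
3. rebuild each living row as the fixed conditional distribution times the
   survival probability, so row sums and the conditional structure are
   preserved exactly.

The reference can be an external table (`read_reference_lifetable()`, which
accepts `Age qx lx Lx` text in the usual abridged-table layout) or the
regime's own implied mortality.

## The multistate life table

`state_occupancy()` iterates the age-specific transition matrices from a
starting age and initial distribution (default: everyone `inactive` at 15,
matching labor-market entry). Expectancies follow from the annual
**year-counting convention**: each age at which a state is occupied
contributes one full year, i.e. Lₓ = lₓ, so with zero mortality remaining
life expectancy at 15 over ages 15–99 is exactly 85 years. External tables
read from disk instead keep (or reconstruct with aₓ = 0.5) their printed
Lₓ. The two conventions are never mixed within a comparison.

`state_expectancies()` sums occupancies; `awle()` adds the employed and
unemployed components into *active* working life expectancy.
`decompose_by_age_band()` splits any expectancy additively over age bands,
and `decompose_change()` attributes the change between two periods to bands
× states. An independent **fundamental-matrix oracle**
(`expectancies_via_fundamental_matrix()`, N = (I − U)⁻¹ on the transient
block) reproduces the iterative expectancies to numerical precision and is
used throughout the test suite.

## Sullivan's method and the comparison

`prevalence_schedule()` computes cross-sectional state prevalences by age
(linear interpolation across unexposed ages, endpoints carried), and
`sullivan_expectancy()` computes

eⱼ(x) = (1/lₓ) Σₖ≥ₓ Lₖ dⱼ(k),

the person-years of the period life table weighted by prevalence. Under a
time-stationary regime — prevalence equal to the chain's conditional
occupancy, the life table built from the chain's implied mortality, the
annual convention, and a matching initial distribution — Sullivan and the
Markov estimator coincide at every starting age; this identity is enforced
in the tests. Away from stationarity they diverge in a characteristic way:
after a labor-market shock the incidence-based estimate reacts immediately
(it uses current transition rates) while Sullivan lags, because the stock of
prevalences still reflects pre-shock history. The bundled
`build_segregated_market_scenario()` reproduces both regimes: with high
track retention Sullivan lags the shock by years; with retention zero the
population mixes quickly and the two estimators re-coincide a few years
after the shock.

`compare_markov_sullivan()` tabulates both series per period with
differences and between-period changes.

## The synthetic register generator

`build_truth_regime()` constructs a fully known transition regime; its
defaults are fixed study conditions, not tuning knobs:

* Gompertz-type mortality q(age) = 3·10⁻⁴ · exp(0.09 (age − 15)), the same
  shape as the bundled reference table;
* alive-destination odds that are additive on the logit scale in origin,
  occupation, sex and year, so the generator lies inside the estimation
  model family and parameter recovery is a genuine consistency check;
* a crisis year (2008) with a −1.2 logit employment shock;
* occupation mixture (0.59, 0.24, 0.11, 0.06) over the four classes.

`simulate_trajectories()` draws seeded individual trajectories (optionally
expanded to monthly spells so the dominant-state ingestion is exercised),
and `write_spells()`/`read_spells()` round-trip the register CSV format.
All randomness flows from a single integer seed.

## Pipeline and command line

`run_pipeline(pipeline_config(...))` executes simulate → ingest → fit →
adjust → life table → Sullivan → comparison, writes every table as CSV plus
a manifest (configuration hash, seed, package and R versions) under the
output directory, and renders a plain-text report. Runs are idempotent:
identical configuration and seed give byte-identical outputs. The same
stages are available individually from the command line:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/worklife-cli.R", package = "worklife"))')" run-all --seed 1 --out-dir out
```

## Limitations

* The Markov assumption ignores duration dependence; long-term unemployment
  scarring, for example, is invisible to a first-order chain.
* Annual dominant states hide within-year churn; short spells are absorbed
  by the dominant state.
* The mortality alignment rescales state-specific mortality
  *proportionally* within each age; differential mortality by labor-market
  state is preserved only up to that common factor.
* Period expectancies describe a synthetic cohort living its whole life
  under one year's rates; they are not forecasts for any real cohort.
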