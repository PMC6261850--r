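# worklife

Multistate working life tables from annual labor-market register data.

`worklife` estimates **working life expectancy** (WLE) — the years a person
can expect to spend employed from a given age onward — together with the
companion expectancies (unemployed, inactive, retired, total remaining
life), using two estimators side by side:

* **Incidence-based (Markov chain)**: a discrete-time multistate life table
  over four living states (`employed`, `unemployed`, `inactive`, `retired`)
  plus absorbing death, ages 15–99, built from one-year transition
  probabilities estimated by subsample-split multinomial logistic
  regression (sex × age band, smooth age effects, calendar-year and
  occupational-class terms).
* **Prevalence-based (Sullivan)**: a period life table weighted by
  cross-sectional state prevalences.

The two coincide under a stationary regime and diverge instructively when
conditions change: the Markov estimate reacts to a labor-market shock in the
period it happens, while Sullivan lags because the stock of prevalences
still embodies pre-shock history. The package quantifies exactly this
comparison, including age-band decompositions of expectancies and of their
change between periods.

Because real register extracts are confidential, the package ships a seeded
**synthetic register generator** with a fully known ground-truth transition
regime. Every stage — spell ingestion with annual dominant-state
assignment, estimation, alignment of aggregate mortality to a reference
life table, life-table construction, decomposition, and the
Markov/Sullivan comparison — is validated against analytic answers
(including an independent fundamental-matrix oracle) in the test suite.
A published reference table of Spanish working life expectancies 2004–2013
is bundled (`spain_wle_table()`) for external anchoring.

See `vignettes/working-life-expectancy.Rmd` for the methods write-up.

## Worked example

Simulate a register, estimate the chain, and compare the two estimators for
women in 2006:

```r
library(worklife)

reg    <- build_truth_regime()                      # known ground truth
spells <- simulate_trajectories(reg, synthetic_config(n = 20000, seed = 42))
py     <- build_person_years(spells, attr(spells, "deaths"))
rec    <- build_transition_records(py, attr(spells, "deaths"))

fit <- fit_transition_models(rec, use_occupation = FALSE)
ps  <- predict_probability_set(fit)

occ <- state_occupancy(ps, sex = "female", occupation = "all", year = 2006)
state_expectancies(occ)
#> # A tibble: 5 × 5
#>   sex    occupation  year state      years
#>   <chr>  <chr>      <dbl> <chr>      <dbl>
#> 1 female all         2006 employed   15.5
#> 2 female all         2006 unemployed  5.44
#> 3 female all         2006 inactive   27.1
#> 4 female all         2006 retired    15.4
#> 5 female all         2006 total      63.4

awle(state_expectancies(occ))                      # Markov, incidence-based
#> [1] 20.91

prev <- prevalence_schedule(py, sex = "female", year = 2006L)
q    <- implied_mortality(ps, "female", "all", 2006)
lt   <- make_lifetable(q$qhat, q$age, convention = "annual")
sullivan_expectancy(lt, prev, state = c("employed", "unemployed"))
#> [1] 21.8                                          # Sullivan, prevalence-based
```

At age 15 a woman under the estimated 2006 regime can expect 15.5 years
employed and 20.9 years in the labor force out of 63.4 remaining years of
life; the Sullivan estimate from the same data is 21.8 years. (The gap
reflects the simulated closed cohort's prevalence history, not estimator
noise — under an exactly stationary regime the two agree to numerical
precision, which the test suite asserts at every start age.)

## Full pipeline

One call runs simulate → ingest → fit → adjust mortality → life tables →
Sullivan → comparison, and writes all tables as CSV plus a manifest and a
plain-text report:

```r
bundle <- run_pipeline(pipeline_config(seed = 1, out_dir = "out"))
bundle$expectancies      # per sex × occupation × period × state
bundle$comparison        # Markov vs Sullivan AWLE by period
```

Runs are idempotent: the same configuration and seed give byte-identical
outputs. The same stages are exposed as a command-line tool:

```sh
CLI="$(Rscript -e 'cat(system.file("scripts/worklife-cli.R", package = "worklife"))')"
Rscript "$CLI" run-all --seed 1 --out-dir out
Rscript "$CLI"                       # lists all subcommands
```

## Reproduction

* **Tests** (testthat, edition 3): from the package root,
  `Rscript -e 'testthat::test_local()'`. The suite covers per-module unit
  and property tests plus an acceptance file that checks the published
  reference table, parameter recovery from a large simulated register,
  the fundamental-matrix oracle, Monte-Carlo agreement, mortality
  alignment, Markov/Sullivan stationarity equivalence, shock-lag behavior,
  and decomposition additivity. One known-failing assertion is deliberate:
  three female rows of the bundled published table are internally
  inconsistent by 0.4–0.7 years (beyond per-cell rounding), so the
  "all rows within 0.3" check fails on exactly those rows.
* **Acceptance script**: against the installed package,

  ```sh
  Rscript scripts/acceptance.R --seed 1 --out results.json
  ```

  writes the headline quantities (published-table checks, pipeline
  expectancies, oracle/adjustment/stationarity residuals, shock response)
  as JSON. All randomness derives from `--seed`; runtime is about a minute.

## Conventions worth knowing

* Annual year-counting: an occupied age contributes one full year
  (L_x = l_x), so with zero mortality e(15) over ages 15–99 is exactly 85.
  External life tables read from disk keep their own midpoint convention.
* Default initial distribution: everyone `inactive` at age 15.
* Recodes: at 65+ unemployment/inactivity count as retired; at 80+ everyone
  alive is retired; a person absent from the register under 65 is inactive.
* Occupational class is the highest ever attained (running maximum).
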