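test_that("prevalence schedules close to 1 and interpolate gaps", {
  py <- tibble::tibble(
    person_id = 1:6, sex = "male",
    year = 2005L, age = c(30L, 30L, 30L, 32L, 32L, 32L),
    state = c("employed", "employed", "employed",
              "employed", "unemployed", "inactive"),
    occupation = NA_character_)
  prev <- prevalence_schedule(py, sex = "male", year = 2005L, ages = 30:32)
  expect_equal(prev$prevalence[prev$age == 30 & prev$state == "employed"], 1)
  # age 31 has no exposure: linear interpolation between 1 and 1/3
  expect_equal(prev$prevalence[prev$age == 31 & prev$state == "employed"], 2 / 3)
  sums <- tapply(prev$prevalence, prev$age, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_error(prevalence_schedule(py, sex = "female", year = 2005L), "no exposure")
})

test_that("endpoint gaps carry the nearest observed value", {
  py <- tibble::tibble(person_id = 1:2, sex = "male", year = 2005L,
                       age = c(40L, 41L), state = "employed",
                       occupation = NA_character_)
  prev <- prevalence_schedule(py, ages = 38:43)
  expect_equal(prev$prevalence[prev$state == "employed"], rep(1, 6))
})

test_that("prevalence of a stationary cohort matches conditional occupancy", {
  reg <- build_truth_regime(regime_params(crisis_magnitude = 0, years = 2004:2012))
  cfg <- synthetic_config(n = 20000, entry_ages = 15L, seed = 13,
                          sex_probs = c(male = 1, female = 0),
                          occupation_probs = c(unskilled_manual = 1,
                                               unskilled_nonmanual = 0,
                                               skilled_manual = 0,
                                               skilled_nonmanual = 0),
                          expand_spells = FALSE, init_from_occupancy = FALSE)
  spl <- simulate_trajectories(reg, cfg)
  py <- build_person_years(spl, attr(spl, "deaths"))
  prev <- prevalence_schedule(py, sex = "male", year = 2012L, ages = 23L)
  occ <- state_occupancy(reg, "male", "unskilled_manual", 2004)
  dd <- occupancy_prevalence(occ)
  n_alive <- attr(prev, "exposure")$exposure[1]
  for (s in wl_states()) {
    p <- dd$prevalence[dd$age == 23 & dd$state == s]
    se <- sqrt(p * (1 - p) / n_alive)
    expect_lt(abs(prev$prevalence[prev$state == s] - p), 3 * se + 1e-9)
  }
})

test_that("Sullivan expectancy has the declared limiting cases", {
  lt <- read_reference_lifetable(synthetic_lifetable_path())
  unit <- tibble::tibble(age = rep(15:99, each = 4),
                         state = rep(wl_states(), 85),
                         prevalence = rep(c(1, 0, 0, 0), 85))
  # d == 1: the life table's own remaining expectancy
  expect_equal(sullivan_expectancy(lt, unit, state = "employed"),
               lifetable_expectancy(lt, 15), tolerance = 1e-9)
  # d == 0
  expect_equal(sullivan_expectancy(lt, unit, state = "unemployed"), 0)
  # d == 0.5: linearity
  half <- unit
  half$prevalence <- rep(c(0.5, 0.5, 0, 0), 85)
  expect_equal(sullivan_expectancy(lt, half, state = "employed"),
               lifetable_expectancy(lt, 15) / 2, tolerance = 1e-9)
  # summing the four states reproduces e_x exactly
  mixed <- unit
  set.seed(4)
  m <- matrix(runif(85 * 4), 85)
  m <- m / rowSums(m)
  mixed$prevalence <- as.vector(t(m))
  tot <- sum(vapply(wl_states(), function(s) sullivan_expectancy(lt, mixed, s),
                    numeric(1)))
  expect_lt(abs(tot - lifetable_expectancy(lt, 15)), 1e-9)
})

test_that("Sullivan is monotone in pointwise-increased prevalence", {
  lt <- read_reference_lifetable(synthetic_lifetable_path())
  base <- tibble::tibble(age = rep(15:99, each = 4),
                         state = rep(wl_states(), 85),
                         prevalence = rep(c(0.4, 0.1, 0.3, 0.2), 85))
  up <- base
  up$prevalence[up$state == "employed"] <-
    pmin(up$prevalence[up$state == "employed"] + 0.1, 1)
  expect_gte(sullivan_expectancy(lt, up, "employed"),
             sullivan_expectancy(lt, base, "employed"))
})

test_that("sullivan_expectancy rejects degenerate inputs", {
  qx <- c(1, rep(1, 84))
  lt <- make_lifetable(qx, 15:99, convention = "annual")
  unit <- tibble::tibble(age = rep(15:99, each = 4),
                         state = rep(wl_states(), 85),
                         prevalence = rep(c(1, 0, 0, 0), 85))
  expect_error(sullivan_expectancy(lt, unit, start_age = 16), "survivors")
  lt2 <- read_reference_lifetable(synthetic_lifetable_path())
  expect_error(sullivan_expectancy(lt2, unit[unit$age < 60, ]), "cover")
})

test_that("awle adds employed and unemployed components", {
  ex <- tibble::tibble(state = c(wl_states(), "total"),
                       years = c(25.6, 6.7, 14.6, 16.7, 63.6))
  expect_equal(awle(ex), 32.3)
  wide <- tibble::tibble(employed = c(10, 20), unemployed = c(1, 2))
  expect_equal(awle(wide)$awle, c(11, 22))
  # zero unemployment: AWLE equals WLE
  ex0 <- tibble::tibble(state = c(wl_states(), "total"),
                        years = c(30, 0, 10, 15, 55))
  expect_equal(awle(ex0), 30)
  expect_error(awle(tibble::tibble(x = 1)), "expects")
})

test_that("Sullivan equals Markov under stationarity at every start age", {
  reg <- truth_regime()
  adjq <- implied_mortality(reg, "female", "skilled_manual", 2006)
  lt <- make_lifetable(adjq$qhat, adjq$age, convention = "annual")
  occ <- state_occupancy(reg, "female", "skilled_manual", 2006)
  prev <- occupancy_prevalence(occ)
  m <- tidyr::pivot_wider(occ, names_from = "state", values_from = "occupancy")
  for (x0 in c(15L, 30L, 50L, 70L, 90L)) {
    row <- m[m$age == x0, wl_states()]
    alive <- sum(row)
    init <- setNames(as.numeric(row) / alive, wl_states())
    markov <- state_expectancies(
      state_occupancy(reg, "female", "skilled_manual", 2006,
                      start_age = x0, init = init))
    qx <- implied_mortality(reg, "female", "skilled_manual", 2006,
                            start_age = x0, init = init)
    ltx <- make_lifetable(qx$qhat, qx$age, convention = "annual")
    for (s in wl_states()) {
      sul <- sullivan_expectancy(ltx, prev, state = s, start_age = x0)
      expect_lt(abs(sul - markov$years[markov$state == s]), 0.1)
    }
  }
})

test_that("comparison table reports levels, differences and trends", {
  mk <- tibble::tibble(year = 2004:2008, awle = c(30, 30, 29, 25, 24))
  sv <- tibble::tibble(year = 2004:2008, awle = c(30, 30, 29.5, 28, 27))
  cmp <- compare_markov_sullivan(mk, sv)
  expect_equal(cmp$period[1], "2004/2005")
  expect_equal(cmp$difference, mk$awle - sv$awle)
  expect_equal(cmp$markov_change[-1], diff(mk$awle))
  # identical inputs: all differences zero
  cmp0 <- compare_markov_sullivan(mk, mk)
  expect_true(all(cmp0$difference == 0))
  # disjoint periods rejected
  expect_error(compare_markov_sullivan(mk, dplyr::mutate(sv, year = year + 100)),
               "overlap")
})

test_that("segregated-market shock: Markov reacts, Sullivan lags", {
  res <- cached("shock_run", {
    sc <- build_segregated_market_scenario(0.9, 0.1, retention = 0.95,
                                           shock_year = 2008)
    cfg <- synthetic_config(n = 20000, entry_ages = 15L, seed = 17,
                            sex_probs = c(male = 1, female = 0),
                            occupation_probs = c(unskilled_manual = 1,
                                                 unskilled_nonmanual = 0,
                                                 skilled_manual = 0,
                                                 skilled_nonmanual = 0),
                            expand_spells = FALSE)
    spl <- simulate_trajectories(sc, cfg)
    py <- build_person_years(spl, attr(spl, "deaths"))
    q <- implied_mortality(sc, "male", "all", 2004)
    lt <- make_lifetable(q$qhat, q$age, convention = "annual")
    markov <- vapply(2004:2012, function(y) {
      awle(state_expectancies(state_occupancy(sc, "male", "all", y)))
    }, numeric(1))
    sullivan <- vapply(2004:2012, function(y) {
      prev <- prevalence_schedule(py, sex = "male", year = y)
      sullivan_expectancy(lt, prev, state = c("employed", "unemployed"))
    }, numeric(1))
    list(markov = markov, sullivan = sullivan)
  })
  yr <- 2004:2012
  m_drop <- res$markov[yr == 2007] - res$markov[yr == 2008]
  s_drop <- res$sullivan[yr == 2007] - res$sullivan[yr == 2008]
  expect_gt(m_drop, s_drop)
  expect_gt(m_drop, 0)
})

test_that("memoryless tracks make the two estimators coincide after a shock", {
  # with retention 0 the chain mixes geometrically, so a few years after the
  # entry shock the cross-sectional prevalence reflects the new regime and
  # Sullivan agrees with the Markov estimate (unlike the lagging
  # high-retention scenario above)
  sc <- build_segregated_market_scenario(0.7, 0.2, retention = 0,
                                         shock_year = 2008)
  cfg <- synthetic_config(n = 60000, entry_ages = 15:84, seed = 19,
                          sex_probs = c(male = 1, female = 0),
                          occupation_probs = c(unskilled_manual = 1,
                                               unskilled_nonmanual = 0,
                                               skilled_manual = 0,
                                               skilled_nonmanual = 0),
                          expand_spells = FALSE)
  spl <- simulate_trajectories(sc, cfg)
  py <- build_person_years(spl, attr(spl, "deaths"))
  # start age 25: an age the aging closed cohort still observes in 2012
  x0 <- 25L
  occ <- state_occupancy(sc, "male", "all", 2012)
  m <- tidyr::pivot_wider(occ, names_from = "state", values_from = "occupancy")
  row <- as.numeric(m[m$age == x0, wl_states()])
  init <- setNames(row / sum(row), wl_states())
  q <- implied_mortality(sc, "male", "all", 2012, start_age = x0, init = init)
  lt <- make_lifetable(q$qhat, q$age, convention = "annual")
  prev <- prevalence_schedule(py, sex = "male", year = 2012L)
  sul <- sullivan_expectancy(lt, prev, state = c("employed", "unemployed"),
                             start_age = x0)
  mar <- awle(state_expectancies(state_occupancy(sc, "male", "all", 2012,
                                                 start_age = x0, init = init)))
  expect_lt(abs(sul - mar), 0.6)
})
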