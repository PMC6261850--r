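test_that("make_lifetable implements both person-year conventions", {
  # zero mortality before 99: annual convention gives e_15 = 85 exactly
  q <- c(rep(0, 84), 1)
  lt <- make_lifetable(q, age = 15:99, convention = "annual")
  expect_equal(lifetable_expectancy(lt, 15), 85)
  expect_equal(lifetable_expectancy(lt, 99), 1)
  # midpoint convention loses half a year in the death year
  lt2 <- make_lifetable(q, age = 15:99, convention = "midpoint")
  expect_equal(lifetable_expectancy(lt2, 15), 84.5)
  # structural invariants
  expect_true(all(diff(lt$lx) <= 0))
  expect_equal(lt$qx[85], 1)
  expect_true(all(lt$Lx >= 0))
})

test_that("reference life table reader parses the bundled fixture", {
  lt <- read_reference_lifetable(synthetic_lifetable_path())
  expect_s3_class(lt, "wl_lifetable")
  expect_equal(lt$age, 15:99)
  expect_equal(lt$qx[85], 1)   # truncated at 99
  expect_equal(lt$lx[1], 1e5)
  expect_true(all(diff(lt$lx) <= 0))
  # l_{x+1} = l_x (1 - q_x), up to the file's two-decimal rounding
  expect_lt(max(abs(lt$lx[-1] - lt$lx[-85] * (1 - lt$qx[-85]))), 0.01)
})

test_that("reader reconstructs lx from qx alone and rejects bad input", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "q_only.csv")
  readr::write_csv(tibble::tibble(age = 15:99, qx = c(rep(0.01, 84), 1)), p)
  lt <- read_reference_lifetable(p)
  expect_equal(lt$lx[1], 1e5)
  expect_equal(lt$lx[2], 1e5 * 0.99)

  p2 <- file.path(dir, "bad_q.csv")
  readr::write_csv(tibble::tibble(age = 15:99, qx = c(1.7, rep(0.01, 83), 1)), p2)
  expect_error(read_reference_lifetable(p2), "row")

  p3 <- file.path(dir, "bad_age.csv")
  readr::write_csv(tibble::tibble(age = c(16, 15, 17:99), qx = 0.01), p3)
  expect_error(read_reference_lifetable(p3), "increasing")
})

test_that("reader is idempotent on an already consistent table", {
  lt <- read_reference_lifetable(synthetic_lifetable_path())
  dir <- withr::local_tempdir()
  p <- file.path(dir, "again.csv")
  readr::write_csv(tibble::tibble(age = lt$age, qx = lt$qx, lx = lt$lx, Lx = lt$Lx), p)
  lt2 <- read_reference_lifetable(p)
  expect_equal(lt2$lx, lt$lx, tolerance = 1e-8)
  expect_equal(lt2$Lx, lt$Lx, tolerance = 1e-8)
})

test_that("absorbing toy: occupancy 1 then 0, total LE = 1", {
  ps <- absorbing_toy(survive = 1)
  occ <- state_occupancy(ps, "male", "all", 2004)
  m <- tidyr::pivot_wider(occ, names_from = "state", values_from = "occupancy")
  expect_equal(sum(m[m$age == 15, wl_states()]), 1)
  expect_equal(sum(m[m$age > 15, wl_states()]), 0)
  ex <- state_expectancies(occ)
  expect_equal(ex$years[ex$state == "total"], 1)
})

test_that("deterministic path: inactive 10 years then death", {
  ps <- absorbing_toy(survive = 10)
  ex <- state_expectancies(state_occupancy(ps, "male", "all", 2004))
  expect_equal(ex$years[ex$state == "inactive"], 10)
  expect_equal(ex$years[ex$state == "employed"], 0)
  expect_equal(ex$years[ex$state == "total"], 10)
})

test_that("geometric toy matches the closed form", {
  ps <- geometric_toy(retention = 0.5)
  occ <- state_occupancy(ps, "male", "all", 2004, init = c(employed = 1))
  emp <- occ$occupancy[occ$state == "employed"]
  expect_equal(emp, 0.5^(0:84))
  ex <- state_expectancies(occ)
  expect_equal(ex$years[ex$state == "employed"], 2 - 0.5^84)
  expect_equal(ex$years[ex$state == "total"], 85)
})

test_that("expectancies are additive and nonnegative", {
  ex <- state_expectancies(
    state_occupancy(truth_regime(), "female", "skilled_nonmanual", 2008))
  expect_true(all(ex$years >= 0))
  expect_lt(abs(sum(ex$years[ex$state != "total"]) - ex$years[ex$state == "total"]),
            1e-9)
})

test_that("forward propagation and fundamental matrix agree", {
  for (s in 1:5) {
    ps <- random_transition_probs(seed = 100 + s)
    e1 <- state_expectancies(state_occupancy(ps, "male", "all", 2004))
    e2 <- expectancies_via_fundamental_matrix(ps, "male", "all", 2004)
    expect_lt(max(abs(e1$years - e2$years)), 1e-10)
  }
})

test_that("raising mortality never raises total life expectancy", {
  ps <- random_transition_probs(seed = 42, max_death = 0.1)
  wide <- tidyr::pivot_wider(as_tibble(ps), names_from = "destination",
                             values_from = "prob")
  bump <- pmin(wide$dead + 0.05, 1)
  alive <- 1 - wide$dead
  scale <- ifelse(alive > 0, (1 - bump) / alive, 0)
  for (st in wl_states()) wide[[st]] <- wide[[st]] * scale
  wide$dead <- bump
  ps2 <- transition_probs(
    tidyr::pivot_longer(wide, dplyr::all_of(wl_all_states()),
                        names_to = "destination", values_to = "prob"),
    provenance = "ground-truth")
  e1 <- state_expectancies(state_occupancy(ps, "male", "all", 2004))
  e2 <- state_expectancies(state_occupancy(ps2, "male", "all", 2004))
  expect_lte(e2$years[e2$state == "total"], e1$years[e1$state == "total"])
})

test_that("age-band decomposition is additive and validated", {
  occ <- state_occupancy(truth_regime(), "male", "unskilled_manual", 2006)
  ex <- state_expectancies(occ)
  dec <- decompose_by_age_band(occ, state = "employed")
  expect_equal(nrow(dec), 6L)
  expect_lt(abs(sum(dec$years) - ex$years[ex$state == "employed"]), 1e-9)
  # one band covering everything returns the full expectancy
  one <- decompose_by_age_band(occ, state = "employed",
                               bands = list(all = 15:99))
  expect_lt(abs(one$years - ex$years[ex$state == "employed"]), 1e-12)
  # overlapping bands rejected
  expect_error(
    decompose_by_age_band(occ, bands = list(a = 15:50, b = 50:99)),
    "partition|overlap")
})

test_that("geometric toy decomposes into first year and the rest", {
  occ <- state_occupancy(geometric_toy(0.5), "male", "all", 2004,
                         init = c(employed = 1))
  dec <- decompose_by_age_band(occ, state = "employed",
                               bands = list(first = 15L, rest = 16:99))
  expect_equal(dec$years, c(1, 1 - 0.5^84))
})

test_that("change decomposition sums to the WLE change", {
  reg <- truth_regime()
  o1 <- state_occupancy(reg, "male", "unskilled_manual", 2006)
  o2 <- state_occupancy(reg, "male", "unskilled_manual", 2009)
  d <- change_decomposition(o1, o2, state = "employed")
  e1 <- state_expectancies(o1)
  e2 <- state_expectancies(o2)
  delta <- e2$years[e2$state == "employed"] - e1$years[e1$state == "employed"]
  expect_lt(abs(sum(d$change) - delta), 1e-9)
  # identical periods decompose to zero
  d0 <- change_decomposition(o1, o1, state = "employed")
  expect_true(all(d0$change == 0))
})

test_that("a shock confined to young-age entry loads the young bands", {
  base <- regime_params(crisis_magnitude = 0, years = 2004:2012)
  reg <- build_truth_regime(base)
  # halve inactive->employed entry for ages 20-29 in the 2008 matrix only
  wide <- tidyr::pivot_wider(as_tibble(reg), names_from = "destination",
                             values_from = "prob")
  hit <- wide$year == 2008 & wide$age >= 20 & wide$age <= 29 &
    wide$origin == "inactive"
  moved <- wide$employed[hit] * 0.5
  wide$employed[hit] <- wide$employed[hit] - moved
  wide$inactive[hit] <- wide$inactive[hit] + moved
  reg2 <- transition_probs(
    tidyr::pivot_longer(wide, dplyr::all_of(wl_all_states()),
                        names_to = "destination", values_to = "prob"),
    provenance = "ground-truth")
  o1 <- state_occupancy(reg2, "male", "unskilled_manual", 2007)
  o2 <- state_occupancy(reg2, "male", "unskilled_manual", 2008)
  d <- change_decomposition(o1, o2, state = "employed")
  total <- sum(d$change)
  young <- d$change[d$band == "20-29"]
  expect_lt(total, 0)
  expect_gt(abs(young) / abs(total), 0.5)
})

test_that("Monte-Carlo years-in-state match analytic expectancies", {
  # moderate-size check; the full 1e6-path version runs in the acceptance suite
  ps <- random_transition_probs(seed = 500, max_death = 0.15)
  ex <- state_expectancies(
    state_occupancy(ps, "male", "all", 2004, init = c(inactive = 1)))
  arr <- worklife:::pset_array(ps, "male", "all", 2004)
  n <- 50000L
  set.seed(99)
  state <- rep(3L, n)   # inactive
  yrs <- matrix(0, n, 4L)
  for (i in 1:85) {
    alive <- state > 0L
    if (!any(alive)) break
    yrs[cbind(which(alive), state[alive])] <-
      yrs[cbind(which(alive), state[alive])] + 1
    p <- arr[i, state[alive], , drop = TRUE]
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    cum <- p[, 1]
    u <- runif(sum(alive))
    dest <- rep(1L, sum(alive))
    for (k in 2:5) {
      dest[u > cum] <- k
      cum <- cum + p[, k]
    }
    state[alive] <- ifelse(dest == 5L, 0L, dest)
  }
  for (j in 1:4) {
    mc <- mean(yrs[, j])
    se <- sd(yrs[, j]) / sqrt(n)
    expect_lt(abs(mc - ex$years[ex$state == wl_states()[j]]), 3 * se + 1e-8)
  }
})
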