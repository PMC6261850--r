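# Shared fixtures for the suite. Expensive objects are built once per test
# run and memoized here.

.wl_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .wl_test_cache)) {
    assign(name, force(expr), envir = .wl_test_cache)
  }
  get(name, envir = .wl_test_cache)
}

# A single-stratum probability set built from a per-age row function.
# `row_fun(age)` returns a 4x5 matrix (origins x destinations, in
# wl_states()/wl_all_states() order).
toy_pset <- function(row_fun, sex = c("male", "female"), occupation = "all",
                     year = 2004L, ages = 15:99) {
  pieces <- lapply(ages, function(a) {
    m <- row_fun(a)
    tibble::tibble(
      occupation = occupation, age = a,
      origin = rep(wl_states(), each = 5L),
      destination = rep(wl_all_states(), times = 4L),
      prob = as.vector(t(m)))
  })
  one_age <- dplyr::bind_rows(pieces)
  full <- tidyr::expand_grid(sex = sex, year = as.integer(year)) |>
    dplyr::cross_join(one_age)
  transition_probs(full, provenance = "ground-truth")
}

# The geometric toy chain: employed self-retains at `retention`, the rest
# moves to inactive; unemployed/inactive/retired are absorbing-alive; no
# death before 99, certain death at 99.
geometric_toy <- function(retention = 0.5) {
  toy_pset(function(age) {
    if (age >= 99) {
      m <- matrix(0, 4, 5)
      m[, 5] <- 1
      return(m)
    }
    m <- diag(4)
    m <- cbind(m, 0)
    m[1, 1] <- retention
    m[1, 3] <- 1 - retention
    m
  })
}

# Certain death after `survive` years spent in the entry state.
absorbing_toy <- function(survive, start_age = 15L, years = 2004L) {
  toy_pset(function(age) {
    m <- matrix(0, 4, 5)
    if (age < start_age + survive - 1L && age < 99) {
      m[cbind(1:4, 1:4)] <- 1
    } else {
      m[, 5] <- 1
    }
    m
  }, year = years)
}

# Default ground-truth regime (study conditions), built once.
truth_regime <- function() cached("truth_regime", build_truth_regime(regime_params()))

# A moderate simulated data set used by several ingestion/estimation tests.
sim_medium <- function() {
  cached("sim_medium", {
    simulate_trajectories(truth_regime(), synthetic_config(n = 6000, seed = 101))
  })
}

sim_medium_py <- function() {
  cached("sim_medium_py", {
    spl <- sim_medium()
    build_person_years(spl, attr(spl, "deaths"))
  })
}

sim_medium_records <- function() {
  cached("sim_medium_records", {
    spl <- sim_medium()
    build_transition_records(sim_medium_py(), attr(spl, "deaths"), final_year = 2013L)
  })
}
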