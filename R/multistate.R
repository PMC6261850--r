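# Multistate (Markov chain) life table: state occupancy by forward
# propagation, state-specific remaining expectancies, a fundamental-matrix
# oracle backend, and additive age-band decompositions of expectancies and
# of their change between periods.
#
# Year-counting convention (D6): a person alive at integer age x contributes
# one full year in the annual state held at x. States are annual
# dominant-state labels, so no fractional within-year correction applies.

#' State occupancy of a synthetic cohort
#'
#' Propagates an initial distribution over the living states forward through
#' the transition probabilities of one stratum: `pi[x + 1] = pi[x] P[x]`
#' restricted to the living states. The stratum's calendar-year matrix is
#' used at every age (period, synthetic-cohort interpretation): the result
#' describes a hypothetical cohort experiencing that period's rates
#' throughout life.
#'
#' @param pset A `transition_probs` set.
#' @param sex,occupation,year Stratum labels.
#' @param start_age First age of the cohort.
#' @param init Named vector: initial distribution over living states at
#'   `start_age` (must sum to 1); default all inactive, the typical state at
#'   age 15.
#' @return Tibble of class `wl_occupancy` (`age`, `state`, `occupancy`:
#'   probability of being alive and in the state at that age), with the
#'   stratum, start age and initial distribution as attributes.
#' @export
state_occupancy <- function(pset, sex, occupation, year,
                            start_age = AGE_MIN, init = c(inactive = 1)) {
  init <- normalize_init(init)
  ages <- start_age:AGE_MAX
  arr <- pset_array(pset, sex, occupation, year, ages = ages)
  pi_mat <- matrix(0, nrow = length(ages), ncol = 4L,
                   dimnames = list(ages, wl_states()))
  pi_mat[1, ] <- init
  for (i in seq_len(length(ages) - 1L)) {
    pi_mat[i + 1L, ] <- pi_mat[i, ] %*% arr[i, , wl_states()]
  }
  out <- as_tibble(pi_mat, rownames = "age") |>
    mutate(age = as.integer(.data$age)) |>
    pivot_longer(-"age", names_to = "state", values_to = "occupancy")
  attr(out, "start_age") <- start_age
  attr(out, "init") <- init
  attr(out, "stratum") <- list(sex = sex, occupation = occupation, year = year)
  class(out) <- c("wl_occupancy", class(tibble()))
  out
}

normalize_init <- function(init) {
  check_states(names(init))
  full <- setNames(numeric(4), wl_states())
  full[names(init)] <- init
  if (any(full < 0) || abs(sum(full) - 1) > 1e-9) {
    abort("init must be a distribution over the living states (non-negative, summing to 1)")
  }
  full
}

occupancy_matrix <- function(occupancy) {
  wide <- pivot_wider(as_tibble(occupancy), names_from = "state",
                      values_from = "occupancy") |> arrange(.data$age)
  m <- as.matrix(wide[, wl_states()])
  rownames(m) <- wide$age
  m
}

#' State-specific remaining life expectancies
#'
#' Sums occupancy over ages: `e_j(x0) = sum_x pi[x, j]`, each occupied year
#' counting one full year. The four state expectancies sum exactly to the
#' total remaining life expectancy at the start age.
#'
#' @param occupancy A [state_occupancy()] result.
#' @return Tibble of class `wl_expectancy` with the stratum labels and one
#'   row per state plus a `total` row (column `years`).
#' @export
state_expectancies <- function(occupancy) {
  stratum <- attr(occupancy, "stratum") %||% list(sex = NA, occupation = NA, year = NA)
  e <- colSums(occupancy_matrix(occupancy))
  out <- tibble(sex = stratum$sex, occupation = stratum$occupation,
                year = stratum$year,
                state = c(wl_states(), "total"),
                years = unname(c(e, sum(e))))
  attr(out, "start_age") <- attr(occupancy, "start_age")
  class(out) <- c("wl_expectancy", class(tibble()))
  out
}

#' Expectancies via the absorbing-chain fundamental matrix
#'
#' Independent backend for the same quantities as [state_expectancies()]:
#' stacks the (age x living state) transient block `U` of the absorbing
#' chain and computes expected visits `N = (I - U)^{-1}`; expected visits to
#' a state, summed over ages and weighted by the initial distribution, equal
#' the forward-propagation expectancies by the algebraic identity
#' `N = I + U + U^2 + ...`. Certain death at age 99 guarantees that `I - U`
#' is invertible.
#'
#' @inheritParams state_occupancy
#' @return Same shape as [state_expectancies()].
#' @export
expectancies_via_fundamental_matrix <- function(pset, sex, occupation, year,
                                                start_age = AGE_MIN,
                                                init = c(inactive = 1)) {
  init <- normalize_init(init)
  ages <- start_age:AGE_MAX
  arr <- pset_array(pset, sex, occupation, year, ages = ages)
  n_age <- length(ages)
  k <- n_age * 4L
  U <- matrix(0, k, k)
  for (i in seq_len(n_age - 1L)) {
    rows <- (i - 1L) * 4L + 1:4
    U[rows, rows + 4L] <- arr[i, , wl_states()]
  }
  IU <- diag(k) - U
  if (abs(det_lower_bound <- min(abs(diag(IU)))) < 1e-14) {
    abort("transient block is singular; certain death at the final age is violated")
  }
  v0 <- numeric(k)
  v0[1:4] <- init
  visits <- solve(t(IU), v0) # t(N) %*% v0, i.e. init %*% N
  e <- rowSums(matrix(visits, nrow = 4L,
                      dimnames = list(wl_states(), NULL)))
  out <- tibble(sex = sex, occupation = occupation, year = year,
                state = c(wl_states(), "total"),
                years = unname(c(e, sum(e))))
  attr(out, "start_age") <- start_age
  class(out) <- c("wl_expectancy", class(tibble()))
  out
}

#' Default age bands for decompositions
#'
#' Six bands: 19 or younger, 20-29, 30-39, 40-49, 50-59, 60 or older; they
#' partition the ages from the start age to 99.
#'
#' @param start_age First age covered.
#' @return Named list of integer age vectors.
#' @export
default_age_bands <- function(start_age = AGE_MIN) {
  list("<=19" = start_age:19, "20-29" = 20:29, "30-39" = 30:39,
       "40-49" = 40:49, "50-59" = 50:59, ">=60" = 60:99)
}

check_bands <- function(bands, ages) {
  all_band_ages <- unlist(bands, use.names = FALSE)
  if (anyDuplicated(all_band_ages) > 0) abort("age bands overlap")
  if (!setequal(all_band_ages, ages)) {
    abort("age bands must partition the ages from the start age to 99")
  }
  invisible(bands)
}

#' Age-band contributions to a state expectancy
#'
#' The contribution of band A to `e_j` is `sum_{x in A} pi[x, j]`: the years
#' of the expectancy realized while the cohort is in that age band.
#' Contributions are additive and sum to the state expectancy.
#'
#' @param occupancy A [state_occupancy()] result.
#' @param state A living state, or `"total"` for all living states combined.
#' @param bands Named list of integer age vectors partitioning the age range
#'   (see [default_age_bands()]).
#' @return Tibble (`band`, `years`) of class `wl_decomposition`.
#' @export
decompose_by_age_band <- function(occupancy, state = "employed",
                                  bands = default_age_bands(attr(occupancy, "start_age"))) {
  m <- occupancy_matrix(occupancy)
  ages <- as.integer(rownames(m))
  check_bands(bands, ages)
  vals <- if (state == "total") rowSums(m) else {
    check_states(state)
    m[, state]
  }
  out <- tibble(band = names(bands),
                years = vapply(bands, function(a) sum(vals[ages %in% a]),
                               numeric(1), USE.NAMES = FALSE))
  attr(out, "state") <- state
  class(out) <- c("wl_decomposition", class(tibble()))
  out
}

#' Age-band decomposition of the change in an expectancy between two periods
#'
#' Per-band difference (period 2 minus period 1) of the contributions of
#' [decompose_by_age_band()]; the bands sum to the total change in the state
#' expectancy between the two periods.
#'
#' @param occupancy1,occupancy2 Occupancies of the two periods, on the same
#'   start age.
#' @inheritParams decompose_by_age_band
#' @return Tibble (`band`, `change`) of class `wl_decomposition`.
#' @export
change_decomposition <- function(occupancy1, occupancy2, state = "employed",
                                 bands = default_age_bands(attr(occupancy1, "start_age"))) {
  if (!identical(attr(occupancy1, "start_age"), attr(occupancy2, "start_age"))) {
    abort("the two occupancies must share the same start age")
  }
  d1 <- decompose_by_age_band(occupancy1, state, bands)
  d2 <- decompose_by_age_band(occupancy2, state, bands)
  out <- tibble(band = d1$band, change = d2$years - d1$years)
  attr(out, "state") <- state
  class(out) <- c("wl_decomposition", class(tibble()))
  out
}

#' Expectancy table across all strata of a probability set
#'
#' Computes the state expectancies for every (sex, occupation, year) stratum
#' and lays them out one period per row with one column per state plus the
#' total — the standard presentation of multistate working-life tables.
#' Periods are labeled `"t/t+1"` because each year-t transition matrix
#' relates two calendar years.
#'
#' @param pset A complete `transition_probs` set.
#' @param start_age,init As in [state_occupancy()].
#' @return Tibble with columns `sex`, `occupation`, `period`, the four state
#'   expectancies and `total`.
#' @export
expectancy_table <- function(pset, start_age = AGE_MIN, init = c(inactive = 1)) {
  strata <- pset_strata(pset)
  rows <- pmap(strata, function(sex, occupation, year) {
    occ <- state_occupancy(pset, sex, occupation, year, start_age, init)
    e <- state_expectancies(occ)
    pivot_wider(as_tibble(e), names_from = "state", values_from = "years") |>
      mutate(period = period_label(year), .after = "occupation") |>
      select(-"year")
  })
  list_rbind(rows)
}

period_label <- function(year) paste0(year, "/", year + 1L)
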