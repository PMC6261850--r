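# Prevalence-based (Sullivan) expectancies and the head-to-head comparison
# with the incidence-based (Markov chain) estimates.

#' Age-specific state prevalence from person-years
#'
#' Raw proportions of the living population in each state at each age, for
#' one sex and calendar year. Ages without exposure are linearly
#' interpolated per state from the neighboring observed ages (endpoint gaps
#' carry the nearest observed value) and renormalized.
#'
#' @param person_years Person-year tibble from [build_person_years()].
#' @param sex,year Stratum selectors (either may be `NULL` to pool).
#' @param ages Age grid of the schedule.
#' @return Tibble of class `wl_prevalence` (`age`, `state`, `prevalence`)
#'   with the per-age exposure in the `"exposure"` attribute.
#' @export
prevalence_schedule <- function(person_years, sex = NULL, year = NULL,
                                ages = AGE_MIN:AGE_MAX) {
  py <- person_years
  if (!is.null(sex)) py <- py[py$sex == sex, ]
  if (!is.null(year)) py <- py[py$year %in% year, ]
  py <- py[py$age %in% ages, ]
  if (nrow(py) == 0) abort("no exposure at any age for the requested stratum")
  counts <- py |>
    count(.data$age, .data$state, name = "n") |>
    complete(age = ages, state = wl_states(), fill = list(n = 0L)) |>
    mutate(exposure = sum(.data$n), .by = "age")
  observed <- counts$exposure > 0
  counts$prevalence <- ifelse(observed, counts$n / pmax(counts$exposure, 1), NA_real_)

  # zero-exposure ages: linear interpolation per state, then renormalize
  if (any(!observed)) {
    counts <- counts |>
      mutate(prevalence = fill_gaps(.data$age, .data$prevalence), .by = "state") |>
      mutate(prevalence = .data$prevalence / sum(.data$prevalence), .by = "age")
  }
  out <- counts |>
    select("age", "state", "prevalence") |>
    arrange(.data$age, match(.data$state, wl_states()))
  attr(out, "exposure") <- distinct(counts, .data$age, .data$exposure)
  class(out) <- c("wl_prevalence", class(tibble()))
  out
}

fill_gaps <- function(age, value) {
  ok <- !is.na(value)
  if (all(ok)) return(value)
  if (sum(ok) == 1L) return(rep(value[ok], length(value)))
  approx(age[ok], value[ok], xout = age, rule = 2)$y
}

#' Prevalence implied by an occupancy matrix
#'
#' The analytic counterpart of [prevalence_schedule()]: occupancy conditional
#' on being alive. Under a time-stationary regime this is the exact period
#' prevalence of the stationary population.
#'
#' @param occupancy A [state_occupancy()] result.
#' @return A `wl_prevalence` tibble.
#' @export
occupancy_prevalence <- function(occupancy) {
  m <- occupancy_matrix(occupancy)
  alive <- rowSums(m)
  d <- m / ifelse(alive > 0, alive, 1)
  d[alive <= 0, ] <- 0
  out <- as_tibble(d) |>
    mutate(age = as.integer(rownames(m)), .before = 1) |>
    pivot_longer(-"age", names_to = "state", values_to = "prevalence")
  class(out) <- c("wl_prevalence", class(tibble()))
  out
}

#' Prevalence-based remaining state expectancy (Sullivan's method)
#'
#' Weights the life table's person-years by the age-specific prevalence of
#' the state: `e_j(x) = (1/l_x) * sum_{k >= x} L_k d_j(k)`. With unit
#' prevalence this reduces to the life table's remaining expectancy; summed
#' over the four states it reproduces `e_x` exactly, since prevalences close
#' to one at every age.
#'
#' @param lifetable A `wl_lifetable` covering the ages of the schedule (use
#'   the annual convention when comparing against the multistate estimates).
#' @param prevalence A `wl_prevalence` schedule.
#' @param state One or several living states; several are summed, so
#'   `c("employed", "unemployed")` yields the labor-force-participation
#'   variant.
#' @param start_age Age `x` from which the expectancy is taken.
#' @return Years spent in the state(s) from `start_age`, as a single number.
#' @export
sullivan_expectancy <- function(lifetable, prevalence,
                                state = "employed", start_age = AGE_MIN) {
  check_states(state)
  d <- prevalence[prevalence$state %in% state, ] |>
    summarise(d = sum(.data$prevalence), .by = "age")
  ages <- start_age:AGE_MAX
  il <- match(ages, lifetable$age)
  id <- match(ages, d$age)
  if (anyNA(il) || anyNA(id)) {
    abort("life table and prevalence schedule must cover all ages from start_age to 99")
  }
  l_start <- lifetable$lx[il[1]]
  if (l_start <= 0) abort("no survivors at the start age in the life table")
  sum(lifetable$Lx[il] * d$d[id]) / l_start
}

#' Active working life expectancy
#'
#' Years expected in the labor force: the employed plus unemployed
#' expectancies. For a long expectancy tibble (one stratum) the result is a
#' single number; for a wide expectancy table an `awle` column is appended.
#'
#' @param x A `wl_expectancy` tibble or a wide expectancy table with
#'   `employed` and `unemployed` columns.
#' @return A number, or `x` with an `awle` column.
#' @export
awle <- function(x) {
  if (all(c("employed", "unemployed") %in% names(x))) {
    return(mutate(x, awle = .data$employed + .data$unemployed))
  }
  if (!all(c("state", "years") %in% names(x))) {
    abort("awle() expects a state-expectancy tibble or a wide expectancy table")
  }
  sum(x$years[x$state %in% c("employed", "unemployed")])
}

#' Compare incidence-based and prevalence-based AWLE series
#'
#' Joins a Markov (per transition period `t/t+1`) and a Sullivan (per year)
#' series of active working life expectancies on the year `t`, and reports
#' per-period levels, differences, and between-period changes of each
#' estimator.
#'
#' @param markov Tibble with columns `year` (or `period`) and `awle`.
#' @param sullivan Tibble with columns `year` and `awle`.
#' @return Tibble (`year`, `period`, `markov`, `sullivan`, `difference`,
#'   `markov_change`, `sullivan_change`), changes relative to the previous
#'   overlapping year.
#' @export
compare_markov_sullivan <- function(markov, sullivan) {
  if (!"year" %in% names(markov) && "period" %in% names(markov)) {
    markov$year <- as.integer(sub("/.*$", "", markov$period))
  }
  joined <- inner_join(
    select(as_tibble(markov), "year", markov = "awle"),
    select(as_tibble(sullivan), "year", sullivan = "awle"),
    by = "year") |>
    arrange(.data$year)
  if (nrow(joined) == 0) abort("the two series have no overlapping periods")
  joined |>
    mutate(period = period_label(.data$year), .after = "year") |>
    mutate(difference = .data$markov - .data$sullivan,
           markov_change = .data$markov - lag(.data$markov),
           sullivan_change = .data$sullivan - lag(.data$sullivan))
}
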