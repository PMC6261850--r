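# Register ingestion: spell records -> annual person-year states -> year-to-
# year transition records, following the annual dominant-state assignment
# rules and the retirement recodes at ages 65+ and 80+.

#' Assign the annual labor-force state from within-year spell durations
#'
#' The annual state is the state in which the individual spent the most time
#' during the year. Ties are broken in favor of the economically more active
#' state (employed > unemployed > retired > inactive). Individuals aged 65
#' or older whose assigned state is unemployed or inactive are counted as
#' retired (they are not entitled to unemployment benefits), and individuals
#' aged 80 or older are always counted as retired. An individual with no
#' spells at all (absent from the register) is inactive below age 65.
#'
#' @param months Named numeric vector of months per state within one year
#'   (may be empty; names from [wl_states()]; repeated names are summed).
#' @param age Integer age in that year.
#' @return A single state code.
#' @examples
#' assign_annual_state(c(unemployed = 7, employed = 4, inactive = 1), age = 40)
#' assign_annual_state(c(unemployed = 12), age = 67)
#' @export
assign_annual_state <- function(months, age) {
  if (length(months) == 0) {
    if (age >= 80) return("retired")
    if (age >= 65) return("retired")
    return("inactive")
  }
  check_states(names(months))
  if (any(months <= 0)) abort("spell durations must be positive")
  if (sum(months) > 12 + 1e-9) abort("months within a person-year must sum to at most 12")
  tot <- tapply(months, names(months), sum)
  cand <- names(tot)[tot == max(tot)]
  state <- state_priority()[min(match(cand, state_priority()))]
  recode_state_by_age(state, age)
}

recode_state_by_age <- function(state, age) {
  state <- ifelse(age >= 65 & state %in% c("unemployed", "inactive"), "retired", state)
  ifelse(age >= 80, "retired", state)
}

#' Highest occupational category ever attained
#'
#' Categories are ordered by skill first, then non-manual over manual:
#' skilled non-manual > skilled manual > unskilled non-manual > unskilled
#' manual. Missing entries are ignored; an all-missing history yields `NA`.
#'
#' @param history Character vector of category codes (chronological order is
#'   irrelevant), possibly containing `NA`.
#' @return A single category code, or `NA_character_`.
#' @examples
#' highest_occupational_category(c("unskilled_nonmanual", "skilled_nonmanual"))
#' highest_occupational_category(c("skilled_manual", "unskilled_nonmanual"))
#' @export
highest_occupational_category <- function(history) {
  check_occupations(history)
  ranks <- match(history, wl_occupations())
  if (all(is.na(ranks))) return(NA_character_)
  wl_occupations()[max(ranks, na.rm = TRUE)]
}

#' Build annual person-years from spell records
#'
#' Collapses within-year spells to one record per person and year using the
#' dominant-state rule of [assign_annual_state()], computes the highest
#' occupational category attained up to each year, and fills years in which
#' a person is absent from the register with the inactive state (recoded to
#' retired from age 65) up to the end of the window or the year before
#' death. Person-years outside ages 15-99 are dropped.
#'
#' @param spells Spell tibble (columns `person_id`, `sex`, `birth_year`,
#'   `year`, `state`, `months`, `occupation`).
#' @param deaths Optional tibble (`person_id`, `death_year`); defaults to the
#'   `deaths` attribute of `spells` if present.
#' @param years Register window; defaults to the range of observed years.
#' @param fill_absent Fill absent years with inactivity (the register
#'   semantics: no contact with social security means inactivity below 65).
#' @return Tibble with columns `person_id`, `sex`, `birth_year`, `year`,
#'   `age`, `state`, `occupation`.
#' @export
build_person_years <- function(spells, deaths = NULL, years = NULL,
                               fill_absent = TRUE) {
  deaths <- deaths %||% attr(spells, "deaths")
  check_states(spells$state)
  check_occupations(spells$occupation)
  if (any(spells$months <= 0)) abort("spell durations must be positive")
  years <- years %||% seq(min(spells$year), max(spells$year))

  per_state <- spells |>
    summarise(months = sum(.data$months),
              .by = c("person_id", "sex", "birth_year", "year", "state"))
  if (any(per_state$months > 12, na.rm = TRUE)) {
    over <- per_state |>
      summarise(m = sum(.data$months), .by = c("person_id", "year")) |>
      filter(.data$m > 12)
    if (nrow(over) > 0) {
      abort(sprintf("months exceed 12 for person %s in year %s",
                    over$person_id[1], over$year[1]))
    }
  }
  # dominant state with the declared tie-break order, fully vectorized
  py <- per_state |>
    arrange(.data$person_id, .data$year, desc(.data$months),
            match(.data$state, state_priority())) |>
    distinct(.data$person_id, .data$year, .keep_all = TRUE) |>
    mutate(age = .data$year - .data$birth_year)

  # highest occupational category attained up to each year
  occ <- spells |>
    mutate(rank = match(.data$occupation, wl_occupations())) |>
    summarise(rank = suppressWarnings(max(.data$rank, na.rm = TRUE)),
              .by = c("person_id", "year")) |>
    mutate(rank = ifelse(is.finite(.data$rank), .data$rank, NA_integer_))
  py <- py |>
    left_join(occ, by = c("person_id", "year")) |>
    arrange(.data$person_id, .data$year) |>
    mutate(rank = cummax_na(.data$rank), .by = "person_id") |>
    mutate(occupation = wl_occupations()[.data$rank])

  if (fill_absent) {
    death_year <- if (!is.null(deaths)) {
      deaths$death_year[match(py$person_id, deaths$person_id)]
    } else {
      rep(NA_integer_, nrow(py))
    }
    bounds <- py |>
      mutate(death_year = death_year) |>
      summarise(sex = .data$sex[1], birth_year = .data$birth_year[1],
                from = min(.data$year),
                to = min(max(years), first(stats::na.omit(.data$death_year)) - 1L,
                         na.rm = TRUE),
                .by = "person_id")
    full <- bounds |>
      filter(.data$to >= .data$from) |>
      reframe(year = seq(.data$from, .data$to),
              sex = .data$sex, birth_year = .data$birth_year,
              .by = "person_id") |>
      mutate(age = .data$year - .data$birth_year)
    py <- full |>
      left_join(select(py, "person_id", "year", "state", "rank"),
                by = c("person_id", "year")) |>
      arrange(.data$person_id, .data$year) |>
      mutate(rank = cummax_na(.data$rank), .by = "person_id") |>
      mutate(state = coalesce(.data$state, "inactive"),
             occupation = wl_occupations()[.data$rank])
  }

  py |>
    mutate(state = recode_state_by_age(.data$state, .data$age)) |>
    filter(.data$age >= AGE_MIN, .data$age <= AGE_MAX) |>
    select("person_id", "sex", "birth_year", "year", "age", "state", "occupation") |>
    arrange(.data$person_id, .data$year)
}

# running maximum that ignores (but propagates past) missing values
cummax_na <- function(x) {
  y <- ifelse(is.na(x), -Inf, x)
  y <- cummax(y)
  ifelse(is.finite(y), as.integer(y), NA_integer_)
}

#' Build year-to-year transition records from person-years
#'
#' Emits one record per adjacent pair of person-years (origin at `t`,
#' destination at `t + 1`). A person present at `t` but absent at `t + 1`
#' moves to death if `t + 1` is the recorded death year, and to inactivity
#' (retirement from age 65) otherwise. No record originates from the final
#' data year, which only serves as a destination year.
#'
#' @param person_years Output of [build_person_years()].
#' @param deaths Optional deaths tibble (`person_id`, `death_year`).
#' @param final_year Last year of the data window.
#' @return Tibble with columns `person_id`, `sex`, `year`, `age`,
#'   `occupation`, `origin`, `destination`.
#' @export
build_transition_records <- function(person_years, deaths = NULL,
                                     final_year = max(person_years$year)) {
  deaths <- deaths %||% attr(person_years, "deaths")
  if (anyDuplicated(person_years[c("person_id", "year")]) > 0) {
    abort("duplicated person-year records")
  }
  py <- arrange(person_years, .data$person_id, .data$year)
  death_year <- if (!is.null(deaths)) {
    deaths$death_year[match(py$person_id, deaths$person_id)]
  } else {
    rep(NA_integer_, nrow(py))
  }
  same_person <- c(py$person_id[-1] == py$person_id[-nrow(py)], FALSE)
  next_year <- c(py$year[-1], NA_integer_)
  next_state <- c(py$state[-1], NA_character_)
  adjacent <- same_person & next_year == py$year + 1L

  destination <- case_when(
    adjacent ~ next_state,
    !is.na(death_year) & death_year == py$year + 1L ~ "dead",
    .default = recode_state_by_age("inactive", py$age + 1L)
  )
  out <- py |>
    mutate(origin = .data$state, destination = destination) |>
    filter(.data$year < final_year) |>
    select("person_id", "sex", "year", "age", "occupation",
           "origin", "destination")
  as_tibble(out)
}
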