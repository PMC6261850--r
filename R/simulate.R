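# Synthetic register generator: seeded individual trajectories drawn from a
# known ground-truth regime, expanded into within-year spell records that
# mimic the structure of an administrative working-life register.

#' Configuration of the synthetic register generator
#'
#' @param n Number of individuals.
#' @param years Calendar years covered by the register window. Everyone
#'   enters at the first year (a closed multi-cohort design; the confidential
#'   register's rolling replacement sampling is deliberately not emulated).
#' @param entry_ages Ages at entry; individuals draw uniformly from this set,
#'   so that all ages of the grid are populated across the window.
#' @param seed Integer seed; identical config and seed give byte-identical
#'   output.
#' @param sex_probs,occupation_probs Mixture proportions (must sum to 1).
#'   The occupation default matches the skew of the register the generator
#'   emulates (59/24/11/6 percent).
#' @param missing_occupation Fraction of individuals whose occupational
#'   category is masked (missing) in the emitted spells.
#' @param expand_spells Expand each person-year into 1-3 within-year spells
#'   whose dominant-duration state equals the annual state (exercises the
#'   ingestion rule). With `FALSE`, one 12-month spell per person-year is
#'   emitted (faster for large runs).
#' @param occupation_mobility If `TRUE`, a fraction of individuals starts one
#'   category below their drawn category and upgrades at a random year,
#'   exercising the highest-category-ever rule.
#' @param init_from_occupancy Draw the state at entry from the regime's own
#'   conditional occupancy at the entry age (period prevalence is then
#'   near-stationary from the first year). Otherwise entrants start inactive
#'   (retired from 65).
#' @return A list of class `wl_config`.
#' @export
synthetic_config <- function(n = 10000,
                             years = 2004:2013,
                             entry_ages = 15:90,
                             seed = 1L,
                             sex_probs = c(male = 0.5, female = 0.5),
                             occupation_probs = c(unskilled_manual = 0.59,
                                                  unskilled_nonmanual = 0.24,
                                                  skilled_manual = 0.11,
                                                  skilled_nonmanual = 0.06),
                             missing_occupation = 0,
                             expand_spells = TRUE,
                             occupation_mobility = FALSE,
                             init_from_occupancy = TRUE) {
  if (abs(sum(occupation_probs) - 1) > 1e-8) abort("occupation_probs must sum to 1")
  if (abs(sum(sex_probs) - 1) > 1e-8) abort("sex_probs must sum to 1")
  if (missing_occupation < 0 || missing_occupation > 1) {
    abort("missing_occupation must be a share in [0, 1]")
  }
  if (!setequal(names(occupation_probs), wl_occupations())) {
    abort("occupation_probs must be named after the four occupational categories")
  }
  if (any(entry_ages < AGE_MIN | entry_ages > AGE_MAX)) {
    abort(sprintf("entry ages must lie within %d-%d", AGE_MIN, AGE_MAX))
  }
  structure(list(n = as.integer(n), years = as.integer(years),
                 entry_ages = as.integer(entry_ages), seed = as.integer(seed),
                 sex_probs = sex_probs, occupation_probs = occupation_probs,
                 missing_occupation = missing_occupation,
                 expand_spells = isTRUE(expand_spells),
                 occupation_mobility = isTRUE(occupation_mobility),
                 init_from_occupancy = isTRUE(init_from_occupancy)),
            class = "wl_config")
}

# categorical draw along the rows of a probability matrix
draw_rows <- function(p, u) {
  cum <- p[, 1]
  idx <- rep(1L, nrow(p))
  for (j in seq_len(ncol(p) - 1L)) {
    idx <- idx + (u > cum)
    if (j < ncol(p) - 1L) cum <- cum + p[, j + 1L]
  }
  idx
}

# initial-state distributions by entry age for one stratum, derived from the
# regime's conditional occupancy starting inactive at 15 (design decision D7)
entry_state_probs <- function(regime, sex, occupation, year, entry_ages) {
  occ <- state_occupancy(regime, sex = sex, occupation = occupation,
                         year = year, start_age = AGE_MIN,
                         init = c(inactive = 1))
  wide <- pivot_wider(occ, names_from = "state", values_from = "occupancy")
  m <- as.matrix(wide[match(entry_ages, wide$age), wl_states()])
  tot <- rowSums(m)
  m[tot <= 0, ] <- rep(c(0, 0, 0, 1), each = sum(tot <= 0))
  m / rowSums(m)
}

#' Simulate register-style trajectories from a transition regime
#'
#' Follows each individual annually from entry until death or the end of the
#' window, drawing destinations from the regime, and expands each
#' person-year into within-year spells. Ages are integer and period-based: a
#' person aged `a` in year `t` is aged `a + 1` in year `t + 1`.
#'
#' @param regime A `transition_probs` set covering all years of the window
#'   except the last (the last year only appears as a destination year).
#' @param config A [synthetic_config()] block.
#' @return A tibble of spell records (`person_id`, `sex`, `birth_year`,
#'   `year`, `state`, `months`, `occupation`) with attributes:
#'   `deaths` (tibble `person_id`, `death_year`), `annual` (the simulated
#'   ground-truth person-years, for round-trip testing), and `config`.
#' @export
simulate_trajectories <- function(regime, config = synthetic_config()) {
  stopifnot(inherits(regime, "transition_probs"))
  years <- config$years
  transition_years <- years[-length(years)]
  missing_years <- setdiff(transition_years, unique(regime$year))
  if (length(missing_years) > 0) {
    abort(paste0("regime lacks transition year(s): ", paste(missing_years, collapse = ", ")))
  }
  regime_occs <- unique(regime$occupation)
  set.seed(config$seed)

  n <- config$n
  sex <- sample(names(config$sex_probs), n, replace = TRUE, prob = config$sex_probs)
  occ_final <- sample(names(config$occupation_probs), n, replace = TRUE,
                      prob = config$occupation_probs)
  entry_age <- config$entry_ages[sample.int(length(config$entry_ages), n,
                                            replace = TRUE)]
  birth_year <- years[1] - entry_age

  # occupational mobility: some individuals start one rank below and upgrade
  occ_rank <- match(occ_final, wl_occupations())
  occ_start <- occ_final
  switch_year <- rep(years[1], n)
  if (config$occupation_mobility) {
    mobile <- runif(n) < 0.3 & occ_rank > 1
    occ_start[mobile] <- wl_occupations()[occ_rank[mobile] - 1L]
    switch_year[mobile] <- sample(years[-1], sum(mobile), replace = TRUE)
  }
  occ_masked <- runif(n) < config$missing_occupation

  # occupation used for transition lookups: the (final) category when the
  # regime is occupation-specific, the pooled stratum otherwise
  occ_lookup <- if ("all" %in% regime_occs) rep("all", n) else occ_final

  # initial states
  state <- rep("inactive", n)
  if (config$init_from_occupancy) {
    for (s in unique(sex)) {
      for (o in unique(occ_lookup)) {
        pick <- sex == s & occ_lookup == o
        if (!any(pick)) next
        probs <- entry_state_probs(regime, s, o, years[1], entry_age[pick])
        state[pick] <- wl_states()[draw_rows(probs, runif(sum(pick)))]
      }
    }
  } else {
    state[entry_age >= 65] <- "retired"
  }
  # entry states must respect the annual-state recodes
  state[entry_age >= 65 & state %in% c("unemployed", "inactive")] <- "retired"
  state[entry_age >= 80] <- "retired"

  alive <- rep(TRUE, n)
  death_year <- rep(NA_integer_, n)
  annual <- vector("list", length(years))

  for (i in seq_along(years)) {
    t <- years[i]
    idx <- which(alive)
    age <- t - birth_year[idx]
    annual[[i]] <- tibble(person_id = idx, sex = sex[idx],
                          birth_year = birth_year[idx], year = t, age = age,
                          state = state[idx], occupation = occ_final[idx])
    if (t == years[length(years)]) break
    lookup <- pset_wide(regime[regime$year == t, ])
    key <- paste(lookup$sex, lookup$occupation, lookup$age, lookup$origin)
    pos <- match(paste(sex[idx], occ_lookup[idx], age, state[idx]), key)
    if (anyNA(pos)) {
      abort(sprintf("regime has no row for %s",
                    paste(sex[idx], occ_lookup[idx], age, state[idx])[which(is.na(pos))[1]]))
    }
    p <- as.matrix(lookup[pos, wl_all_states()])
    dest <- draw_rows(p, runif(length(idx)))
    died <- dest == 5L
    death_year[idx[died]] <- t + 1L
    alive[idx[died]] <- FALSE
    state[idx[!died]] <- wl_states()[dest[!died]]
  }

  annual <- list_rbind(annual)
  if (config$occupation_mobility) {
    up <- match(annual$person_id, seq_len(n))
    early <- annual$year < switch_year[up]
    annual$occupation <- ifelse(early, occ_start[up], occ_final[up])
  }

  spells <- expand_person_years(annual, expand = config$expand_spells)
  spells$occupation[occ_masked[spells$person_id]] <- NA_character_

  deaths <- tibble(person_id = which(!is.na(death_year)),
                   death_year = death_year[!is.na(death_year)])
  attr(spells, "deaths") <- deaths
  attr(spells, "annual") <- annual
  attr(spells, "config") <- config
  spells
}

# expand annual states into 1-3 within-year spells; the annual state always
# receives 7-12 of the 12 months so the dominant-state rule recovers it
expand_person_years <- function(annual, expand = TRUE) {
  cols <- c("person_id", "sex", "birth_year", "year", "state", "months", "occupation")
  if (!expand) {
    out <- annual
    out$months <- 12L
    return(as_tibble(out[cols]))
  }
  n <- nrow(annual)
  k <- sample.int(3L, n, replace = TRUE, prob = c(0.55, 0.3, 0.15))
  extra <- integer(n)
  extra[k == 2L] <- sample(1:5, sum(k == 2L), replace = TRUE)
  extra[k == 3L] <- sample(2:5, sum(k == 3L), replace = TRUE)
  m_main <- 12L - extra
  s1 <- integer(n)
  three <- k == 3L
  s1[three] <- 1L + floor(runif(sum(three)) * (extra[three] - 1L))
  s2 <- extra - s1

  # the three non-dominant living states for each row
  others_tab <- t(vapply(wl_states(), function(s) setdiff(wl_states(), s),
                         character(3)))
  others <- others_tab[match(annual$state, wl_states()), , drop = FALSE]
  i1 <- sample.int(3L, n, replace = TRUE)
  j <- sample.int(2L, n, replace = TRUE)
  rest_tab <- rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  i2 <- rest_tab[cbind(i1, j)]
  o1 <- others[cbind(seq_len(n), i1)]
  o2 <- others[cbind(seq_len(n), i2)]

  main <- annual
  main$months <- m_main
  second <- annual[k >= 2L, ]
  second$state <- o1[k >= 2L]
  second$months <- ifelse(three[k >= 2L], s1[k >= 2L], extra[k >= 2L])
  third <- annual[three, ]
  third$state <- o2[three]
  third$months <- s2[three]
  out <- bind_rows(main, second, third) |>
    arrange(.data$person_id, .data$year, desc(.data$months))
  as_tibble(out[cols])
}

#' Read and write spell records
#'
#' Spell output uses a plain CSV dialect with header
#' `person_id, sex, birth_year, year, state, months, occupation`; the same
#' dialect is accepted for user-supplied register extracts. Deaths travel in
#' a companion CSV (`person_id, death_year`).
#'
#' @param spells Spell tibble as produced by [simulate_trajectories()].
#' @param path,deaths_path Output/input file paths.
#' @return `write_spells()` returns `path` invisibly; `read_spells()`
#'   returns a spell tibble (with a `deaths` attribute when
#'   `deaths_path` is given).
#' @export
write_spells <- function(spells, path, deaths_path = NULL) {
  readr::write_csv(spells[, c("person_id", "sex", "birth_year", "year",
                              "state", "months", "occupation")], path)
  deaths <- attr(spells, "deaths")
  if (!is.null(deaths_path) && !is.null(deaths)) {
    readr::write_csv(deaths, deaths_path)
  }
  invisible(path)
}

#' @rdname write_spells
#' @export
read_spells <- function(path, deaths_path = NULL) {
  spells <- readr::read_csv(path, col_types = readr::cols(
    person_id = readr::col_integer(), sex = readr::col_character(),
    birth_year = readr::col_integer(), year = readr::col_integer(),
    state = readr::col_character(), months = readr::col_integer(),
    occupation = readr::col_character()))
  check_states(spells$state)
  check_occupations(spells$occupation)
  if (!is.null(deaths_path)) {
    attr(spells, "deaths") <- readr::read_csv(deaths_path, col_types = readr::cols(
      person_id = readr::col_integer(), death_year = readr::col_integer()))
  }
  spells
}
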