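# State space, occupational categories, and the transition-probability container
# shared by every stage of the pipeline.

AGE_MIN <- 15L
AGE_MAX <- 99L

#' Labor-force state and occupational-category vocabularies
#'
#' The living population is partitioned into four annual labor-force states;
#' death is the absorbing fifth state. Occupational categories combine a
#' skill dimension with a manual/non-manual dimension and are returned in
#' increasing rank under the "highest category ever attained" total order
#' (skill dominates, then non-manual over manual).
#'
#' @return Character vectors of state or category codes.
#' @examples
#' wl_states()
#' wl_occupations()
#' @export
wl_states <- function() {
  c("employed", "unemployed", "inactive", "retired")
}

#' @rdname wl_states
#' @export
wl_all_states <- function() {
  c(wl_states(), "dead")
}

#' @rdname wl_states
#' @export
wl_occupations <- function() {
  c("unskilled_manual", "unskilled_nonmanual", "skilled_manual", "skilled_nonmanual")
}

wl_sexes <- function() c("male", "female")

# tie-break priority when annual durations are equal (D1): favor the
# economically active state
state_priority <- function() c("employed", "unemployed", "retired", "inactive")

check_states <- function(x, allow_dead = FALSE, what = "state") {
  ok <- if (allow_dead) wl_all_states() else wl_states()
  bad <- setdiff(unique(x), ok)
  if (length(bad) > 0) {
    abort(sprintf("unknown %s code(s): %s", what, paste(bad, collapse = ", ")))
  }
  invisible(x)
}

check_occupations <- function(x, allow_missing = TRUE) {
  vals <- unique(x)
  if (allow_missing) vals <- vals[!is.na(vals)]
  bad <- setdiff(vals, c(wl_occupations(), "all"))
  if (length(bad) > 0) {
    abort(sprintf("unknown occupational category code(s): %s", paste(bad, collapse = ", ")))
  }
  invisible(x)
}

#' Construct a transition-probability set
#'
#' A transition-probability set is a long-format tibble holding
#' `Pr(Z[t+1] = destination | Z[t] = origin)` for every stratum cell
#' (sex, occupational category, calendar year `t`, age at `t`). It is the
#' exchange format between the generator, the estimators, the mortality
#' alignment, and the life-table stage.
#'
#' Invariants enforced on construction: probabilities lie in `[0, 1]` and
#' every `(sex, occupation, year, age, origin)` row sums to 1 (within
#' `1e-10`) unless `partial = TRUE` (used for raw empirical frequencies
#' where zero-exposure cells are absent).
#'
#' @param data Data frame with columns `sex`, `occupation`, `year`, `age`,
#'   `origin`, `destination`, `prob`.
#' @param provenance One of `"ground-truth"`, `"model-based"`, `"empirical"`,
#'   `"adjusted"`.
#' @param partial Allow an incomplete grid (zero-exposure cells missing).
#' @return A tibble of class `transition_probs`.
#' @export
transition_probs <- function(data,
                             provenance = c("ground-truth", "model-based",
                                            "empirical", "adjusted"),
                             partial = FALSE) {
  provenance <- match.arg(provenance)
  needed <- c("sex", "occupation", "year", "age", "origin", "destination", "prob")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("transition_probs data lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  check_states(data$origin)
  check_states(data$destination, allow_dead = TRUE)
  check_occupations(data$occupation, allow_missing = FALSE)
  if (any(data$prob < -1e-12 | data$prob > 1 + 1e-12)) {
    abort("transition probabilities must lie in [0, 1]")
  }
  out <- as_tibble(data[needed])
  out$prob <- pmin(pmax(out$prob, 0), 1)
  if (!partial) {
    sums <- out |>
      summarise(s = sum(.data$prob),
                .by = c("sex", "occupation", "year", "age", "origin"))
    if (any(abs(sums$s - 1) > 1e-10)) {
      abort("every destination row of a transition-probability set must sum to 1")
    }
  }
  attr(out, "provenance") <- provenance
  attr(out, "partial") <- partial
  class(out) <- c("transition_probs", class(tibble()))
  out
}

#' @export
print.transition_probs <- function(x, ...) {
  cat(sprintf("<transition_probs> provenance: %s | %d strata x %d ages\n",
              attr(x, "provenance"),
              nrow(distinct(as_tibble(x), .data$sex, .data$occupation, .data$year)),
              length(unique(x$age))))
  NextMethod()
}

pset_provenance <- function(pset) attr(pset, "provenance") %||% "ground-truth"

pset_strata <- function(pset) {
  distinct(as_tibble(pset), .data$sex, .data$occupation, .data$year) |>
    arrange(.data$sex, .data$occupation, .data$year)
}

# Extract one stratum as a [age, origin, destination] array, checking
# grid completeness. Rows are ordered 15..99 x 4 origins x 5 destinations.
pset_array <- function(pset, sex, occupation, year,
                       ages = AGE_MIN:AGE_MAX) {
  sel <- pset[pset$sex == sex & pset$occupation == occupation &
                pset$year == year & pset$age %in% ages, , drop = FALSE]
  n_expect <- length(ages) * length(wl_states()) * length(wl_all_states())
  if (nrow(sel) != n_expect) {
    abort(sprintf(
      "stratum sex=%s occupation=%s year=%s is missing from the probability set (or incomplete: %d of %d rows)",
      sex, occupation, year, nrow(sel), n_expect))
  }
  arr <- array(
    0, dim = c(length(ages), 4L, 5L),
    dimnames = list(age = ages, origin = wl_states(), destination = wl_all_states()))
  idx <- cbind(match(sel$age, ages),
               match(sel$origin, wl_states()),
               match(sel$destination, wl_all_states()))
  arr[idx] <- sel$prob
  arr
}

# Long <-> wide (one column per destination) conversions used by the
# boundary rules and the mortality alignment.
pset_wide <- function(pset) {
  pivot_wider(as_tibble(pset),
              names_from = "destination", values_from = "prob",
              values_fill = 0)
}

pset_long <- function(wide, provenance, partial = FALSE) {
  long <- pivot_longer(wide, cols = all_of(wl_all_states()),
                       names_to = "destination", values_to = "prob")
  transition_probs(long, provenance = provenance, partial = partial)
}

# Boundary rules shared by the generator and the estimators. With ages
# indexed at t (destination state is held at age t+1):
#   * destination age >= 65: unemployed/inactive mass moves to retired
#     (mirrors the annual-state recode of the ingestion rules);
#   * destination age >= 80: all non-death mass moves to retired;
#   * age 99: death is certain.
# Rows are renormalized exactly afterwards.
enforce_boundaries <- function(wide) {
  dest_age <- wide$age + 1L
  move_ui <- dest_age >= 65L
  wide$retired <- wide$retired + ifelse(move_ui, wide$unemployed + wide$inactive, 0)
  wide$unemployed <- ifelse(move_ui, 0, wide$unemployed)
  wide$inactive <- ifelse(move_ui, 0, wide$inactive)
  move_e <- dest_age >= 80L
  wide$retired <- wide$retired + ifelse(move_e, wide$employed, 0)
  wide$employed <- ifelse(move_e, 0, wide$employed)
  certain <- wide$age >= AGE_MAX
  for (s in wl_states()) wide[[s]] <- ifelse(certain, 0, wide[[s]])
  wide$dead <- ifelse(certain, 1, wide$dead)
  tot <- wide$employed + wide$unemployed + wide$inactive + wide$retired + wide$dead
  bad <- tot <= 0
  if (any(bad)) {
    # defensive: an all-zero row cannot be renormalized
    wide$dead[bad] <- 1
    tot[bad] <- 1
  }
  for (s in wl_all_states()) wide[[s]] <- wide[[s]] / tot
  wide
}

#' Generate a random valid transition-probability set
#'
#' Draws Dirichlet-like destination rows for a single stratum and applies the
#' boundary rules (retirement recodes at ages 65+/80+, certain death at 99).
#' Intended for property-style testing of the life-table backends; the
#' resulting regime has no demographic interpretation.
#'
#' @param year Calendar year label of the stratum.
#' @param sex,occupation Stratum labels.
#' @param max_death Upper bound for the raw death probability at each age.
#' @param seed Optional integer seed (local to this call).
#' @return A `transition_probs` tibble with a single stratum.
#' @export
random_transition_probs <- function(year = 2004L, sex = "male",
                                    occupation = "all", max_death = 0.2,
                                    seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  grid <- expand_grid(sex = sex, occupation = occupation, year = as.integer(year),
                      age = AGE_MIN:AGE_MAX, origin = wl_states())
  raw <- matrix(stats::rgamma(nrow(grid) * 4L, shape = 1), ncol = 4L)
  raw <- raw / rowSums(raw)
  q <- runif(nrow(grid), 0, max_death)
  wide <- grid
  for (i in seq_along(wl_states())) wide[[wl_states()[i]]] <- raw[, i] * (1 - q)
  wide$dead <- q
  pset_long(enforce_boundaries(wide), provenance = "ground-truth")
}
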