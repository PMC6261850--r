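# Mortality alignment: rescale the state-specific death probabilities of a
# transition-probability set so that the implied aggregate mortality matches
# an external reference life table, leaving the conditional-on-survival
# transition structure untouched.

#' Aggregate mortality implied by a probability set
#'
#' The occupancy-weighted aggregate death probability at each age of one
#' stratum: weights are the living-state composition of the synthetic cohort
#' at that age.
#'
#' @inheritParams state_occupancy
#' @return Tibble (`age`, `qhat`).
#' @export
implied_mortality <- function(pset, sex, occupation, year,
                              start_age = AGE_MIN, init = c(inactive = 1)) {
  ages <- start_age:AGE_MAX
  arr <- pset_array(pset, sex, occupation, year, ages = ages)
  tibble(age = ages, qhat = implied_q(arr, normalize_init(init)))
}

# occupancy weights and aggregate q from a stratum array
implied_q <- function(arr, init) {
  n_age <- dim(arr)[1]
  pi_mat <- matrix(0, n_age, 4L)
  pi_mat[1, ] <- init
  for (i in seq_len(n_age - 1L)) {
    pi_mat[i + 1L, ] <- pi_mat[i, ] %*% arr[i, , wl_states()]
  }
  alive <- rowSums(pi_mat)
  w <- pi_mat / ifelse(alive > 0, alive, 1)
  # where the cohort is extinct, weight states equally (the scale there is
  # irrelevant for expectancies but keeps the target well defined)
  w[alive <= 0, ] <- 0.25
  rowSums(w * arr[, , "dead"])
}

#' Align a probability set's mortality with a reference life table
#'
#' Iteratively scales the state-specific death probabilities at each age by
#' a common factor so that the occupancy-weighted aggregate death
#' probability equals the reference `q_x`; probabilities of the living
#' destinations are renormalized proportionally, so the ratios between
#' non-death destinations — the conditional-on-survival transition structure
#' — are preserved exactly. Occupancy weights are recomputed from the
#' current set at every iteration. After convergence the chain's total
#' remaining life expectancy at the start age reproduces the reference
#' table's (annual-convention) expectancy.
#'
#' A scale factor that would push a death probability above 1 is capped at
#' 1; the remaining deficit is reported per cell in the adjustment report.
#'
#' @param pset A complete `transition_probs` set.
#' @param reference A `wl_lifetable`, or a named list with one table per sex
#'   (`male`, `female`); each stratum is matched against its sex's table.
#' @param init Initial distribution used for the occupancy weights.
#' @param start_age Age from which occupancy is propagated.
#' @param tol Convergence tolerance on `max |qhat_x - q_x|`.
#' @param max_iter Iteration cap.
#' @return The adjusted `transition_probs` (provenance `"adjusted"`), with an
#'   `"adjustment"` attribute: per-stratum report (iterations, residual gap,
#'   capped cells) and per-age cumulative scale factors.
#' @export
adjust_probability_set <- function(pset, reference, init = c(inactive = 1),
                                   start_age = AGE_MIN, tol = 1e-6,
                                   max_iter = 50) {
  init <- normalize_init(init)
  ages <- start_age:AGE_MAX
  get_reference_q <- function(sex) {
    ref <- if (inherits(reference, "wl_lifetable")) reference else reference[[sex]]
    if (is.null(ref)) abort(sprintf("no reference life table for sex '%s'", sex))
    i <- match(ages, ref$age)
    if (anyNA(i)) abort("reference life table does not cover ages of the probability set")
    q <- ref$qx[i]
    q[length(q)] <- 1
    q
  }

  strata <- pset_strata(pset)
  report <- vector("list", nrow(strata))
  scales <- vector("list", nrow(strata))
  pieces <- vector("list", nrow(strata))

  for (s in seq_len(nrow(strata))) {
    sx <- strata$sex[s]; oc <- strata$occupation[s]; yr <- strata$year[s]
    arr <- pset_array(pset, sx, oc, yr, ages = ages)
    q_ref <- get_reference_q(sx)
    q0 <- arr[, , "dead"]
    # conditional-on-survival destination distribution: invariant under the
    # adjustment, so fix it once and rebuild living rows from it each
    # iteration (this also recovers living mass when a capped cell is later
    # scaled back below 1). Cells that already had certain death keep
    # stay-in-state as the (never used) conditional distribution.
    cond <- arr[, , wl_states(), drop = FALSE]
    denom <- 1 - q0
    for (d in wl_states()) {
      cond[, , d] <- ifelse(denom > 0, cond[, , d] / denom, 0)
    }
    for (j in seq_along(wl_states())) {
      cond[denom[, j] <= 0, j, wl_states()[j]] <- 1
    }
    iter <- 0L
    gap <- Inf
    capped <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      qhat <- implied_q(arr, init)
      gap <- max(abs(qhat - q_ref))
      if (gap < tol) break
      f <- ifelse(qhat > 0, q_ref / qhat, NA_real_)
      qd <- arr[, , "dead"]
      new_qd <- qd * ifelse(is.na(f), 1, f)
      # zero implied mortality with a positive target: assign the target
      # uniformly across origin states
      zero_rows <- is.na(f) & q_ref > 0
      new_qd[zero_rows, ] <- q_ref[zero_rows]
      over <- new_qd > 1
      capped <- capped + sum(over & new_qd != qd)
      new_qd <- pmin(new_qd, 1)
      for (d in wl_states()) arr[, , d] <- cond[, , d] * (1 - new_qd)
      arr[, , "dead"] <- new_qd
    }
    qhat <- implied_q(arr, init)
    report[[s]] <- tibble(sex = sx, occupation = oc, year = yr,
                          iterations = iter, max_gap = max(abs(qhat - q_ref)),
                          capped_cells = capped)
    scale_age <- ifelse(rowMeans(q0) > 0, rowMeans(arr[, , "dead"]) / rowMeans(q0),
                        NA_real_)
    scales[[s]] <- tibble(sex = sx, occupation = oc, year = yr, age = ages,
                          scale = scale_age)
    long <- expand_grid(age = ages, origin = wl_states(),
                        destination = wl_all_states())
    long$prob <- arr[cbind(match(long$age, ages), match(long$origin, wl_states()),
                           match(long$destination, wl_all_states()))]
    pieces[[s]] <- mutate(long, sex = sx, occupation = oc, year = yr, .before = 1)
  }

  out <- transition_probs(list_rbind(pieces), provenance = "adjusted")
  residual <- list_rbind(report)
  if (any(residual$max_gap >= tol)) {
    warn(sprintf("mortality alignment left a residual gap of up to %.2e (capped cells: %d)",
                 max(residual$max_gap), sum(residual$capped_cells)))
  }
  attr(out, "adjustment") <- list(report = residual, scale_factors = list_rbind(scales))
  out
}
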