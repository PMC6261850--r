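# Transition-probability estimation: subsample-split multinomial logistic
# regression with a cubic B-spline age basis, year indicators, occupational
# category and occupation x year interactions; plus a raw-frequency
# tabulation used as an independent oracle for model validation.

AGE_BANDS <- c("15-29", "30-54", "55-64", "65-79", "80-99")

#' Age band of the estimation subsamples
#'
#' The data are split by sex and five age groups (15-29, 30-54, 55-64,
#' 65-79, 80-99); each of the ten cells is fitted separately, which allows
#' discontinuities at the band edges and implicit interactions of age and
#' sex with all covariates.
#'
#' @param age Integer ages.
#' @return Character vector with the five band labels.
#' @export
age_band <- function(age) {
  as.character(cut(age, breaks = c(15, 30, 55, 65, 80, 100), right = FALSE,
                   labels = AGE_BANDS))
}

band_ages <- function(band) {
  lims <- list("15-29" = 15:29, "30-54" = 30:54, "55-64" = 55:64,
               "65-79" = 65:79, "80-99" = 80:99)
  lims[[band]]
}

#' Fit subsample-split multinomial transition models
#'
#' For each sex x age-band subsample, fits a maximum-likelihood multinomial
#' logistic regression of the destination state on the origin state, a cubic
#' B-spline basis in age, calendar-year indicators (first year as
#' reference; the final data year never appears as an origin year and so has
#' no indicator), occupational-category indicators and occupation x year
#' interactions. Records are aggregated to covariate-cell counts before
#' fitting, which leaves the likelihood unchanged and makes the fits cheap
#' even for millions of transitions. A small ridge penalty (`decay`) guards
#' against separation in sparse cells; destinations never observed in a
#' subsample are treated as structural zeros.
#'
#' @param records Transition records from [build_transition_records()].
#' @param use_occupation Include occupational category (records with missing
#'   category are dropped, with a message). `FALSE` reproduces the
#'   total-population analysis.
#' @param spline_df Degrees of freedom of the cubic B-spline in age
#'   (default 8: five interior knots at age quantiles within the band).
#' @param decay Ridge penalty passed to the optimizer.
#' @return An object of class `transition_model_set`.
#' @export
fit_transition_models <- function(records, use_occupation = TRUE,
                                  spline_df = 8, decay = 1e-6) {
  check_states(records$origin)
  check_states(records$destination, allow_dead = TRUE)
  if (use_occupation) {
    n_miss <- sum(is.na(records$occupation))
    if (n_miss > 0) {
      inform(sprintf("dropping %d transition(s) with missing occupational category", n_miss))
      records <- records[!is.na(records$occupation), ]
    }
  } else {
    records$occupation <- "all"
  }
  records$band <- as.character(age_band(records$age))
  years <- sort(unique(records$year))

  cells <- records |>
    count(.data$sex, .data$band, .data$origin, .data$age, .data$year,
          .data$occupation, .data$destination, name = "n")

  subsamples <- expand_grid(sex = wl_sexes(), band = AGE_BANDS) |>
    filter(paste(.data$sex, .data$band) %in% paste(cells$sex, cells$band))
  fits <- pmap(subsamples, function(sex, band) {
    dat <- cells[cells$sex == sex & cells$band == band, ]
    fit_one_subsample(dat, sex = sex, band = band,
                      spline_df = spline_df, decay = decay)
  })
  names(fits) <- paste(subsamples$sex, subsamples$band)

  structure(list(fits = fits, use_occupation = use_occupation,
                 years = years, spline_df = spline_df, decay = decay),
            class = "transition_model_set")
}

fit_one_subsample <- function(dat, sex, band, spline_df, decay) {
  destinations <- sort(unique(dat$destination))
  origins <- sort(unique(dat$origin))
  occupations <- sort(unique(dat$occupation))
  yrs <- sort(unique(dat$year))
  n_ages <- length(unique(dat$age))

  info <- list(sex = sex, band = band, destinations = destinations,
               origins = origins, occupations = occupations, years = yrs,
               n = sum(dat$n), n_cells = nrow(dat))
  if (length(destinations) == 1L) {
    warn(sprintf("subsample %s %s: single destination '%s' observed; degenerate fit",
                 sex, band, destinations))
    info$model <- NULL
    info$loglik <- 0
    info$loglik_null <- 0
    info$edf <- 0L
    return(info)
  }

  terms <- character(0)
  if (length(origins) > 1L) terms <- c(terms, "origin")
  if (n_ages >= 5L) {
    # boundary knots pinned to the band edges so that prediction over the
    # full band never extrapolates beyond the spline basis
    rng <- range(band_ages(band))
    terms <- c(terms, sprintf("splines::bs(age, df = %d, Boundary.knots = c(%d, %d))",
                              min(spline_df, n_ages - 1L), rng[1], rng[2]))
  } else if (n_ages >= 2L) {
    terms <- c(terms, sprintf("stats::poly(age, %d)", n_ages - 1L))
  }
  if (length(yrs) > 1L) terms <- c(terms, "factor(year)")
  if (length(occupations) > 1L) {
    terms <- c(terms, "occupation")
    if (length(yrs) > 1L) terms <- c(terms, "occupation:factor(year)")
  }
  if (length(terms) == 0L) terms <- "1"
  fml <- stats::as.formula(paste("destination ~", paste(terms, collapse = " + ")))

  dat$destination <- factor(dat$destination, levels = destinations)
  fit <- tryCatch(
    nnet::multinom(fml, data = dat, weights = dat$n, decay = decay,
                   trace = FALSE, maxit = 600, MaxNWts = 20000, model = TRUE),
    error = function(e) {
      abort(sprintf("multinomial fit failed in subsample %s %s: %s",
                    sex, band, conditionMessage(e)))
    })
  info$model <- fit
  # likelihoods computed directly (the ridge penalty is excluded)
  p <- predict_probs(fit, dat, destinations)
  ll <- sum(dat$n * log(pmax(p[cbind(seq_len(nrow(dat)),
                                     match(dat$destination, destinations))], 1e-300)))
  marg <- tapply(dat$n, dat$destination, sum)
  info$loglik <- ll
  info$loglik_null <- sum(marg * log(marg / sum(marg)))
  info$edf <- length(coef(fit))
  info
}

# predicted probability matrix over the given destination levels
# (multinom returns a bare vector when only two classes are present)
predict_probs <- function(fit, newdata, destinations) {
  p <- predict(fit, newdata = newdata, type = "probs")
  if (is.null(dim(p))) {
    if (length(fit$lev) == 2L) {
      p <- cbind(1 - p, p)
      colnames(p) <- fit$lev
    } else {
      p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
    }
  }
  p <- p[, destinations, drop = FALSE]
  unname(as.matrix(p))
}

#' @export
print.transition_model_set <- function(x, ...) {
  cat(sprintf("<transition_model_set> %d subsample fits | occupation: %s | years %s-%s\n",
              length(x$fits), if (x$use_occupation) "included" else "excluded",
              min(x$years), max(x$years)))
  invisible(x)
}

#' @describeIn fit_transition_models One row per subsample with fit summaries
#'   (`loglik` always at least the intercept-only `loglik_null`).
#' @param x,object A `transition_model_set`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.transition_model_set <- function(x, ...) {
  map_dfr(x$fits, function(f) {
    tibble(sex = f$sex, band = f$band, n = f$n, n_cells = f$n_cells,
           n_destinations = length(f$destinations), edf = f$edf,
           loglik = f$loglik, loglik_null = f$loglik_null,
           deviance = -2 * f$loglik)
  })
}

#' @describeIn fit_transition_models Long tibble of model coefficients.
#' @exportS3Method generics::tidy
tidy.transition_model_set <- function(x, ...) {
  map_dfr(x$fits, function(f) {
    if (is.null(f$model)) return(tibble())
    cf <- coef(f$model)
    if (is.null(dim(cf))) {
      cf <- matrix(cf, nrow = 1, dimnames = list(f$destinations[2], names(cf)))
    }
    as_tibble(cf, rownames = "destination") |>
      pivot_longer(-"destination", names_to = "term", values_to = "estimate") |>
      mutate(sex = f$sex, band = f$band, .before = 1)
  })
}

#' Materialize the fitted models on the full probability grid
#'
#' Predicts transition probabilities for every combination of sex,
#' occupational category, calendar year, age 15-99 and origin state, then
#' enforces the boundary rules (destination-age retirement recodes at 65+
#' and 80+, certain death at 99) and renormalizes each row exactly. Origin
#' states never observed in a subsample receive stay-in-state rows (they are
#' unreachable under the initial distributions used downstream); predicted
#' age curves may jump at band edges because bands are fitted separately.
#'
#' @param model_set A [fit_transition_models()] result.
#' @return A `transition_probs` tibble with provenance `"model-based"`.
#' @export
predict_probability_set <- function(model_set) {
  stopifnot(inherits(model_set, "transition_model_set"))
  pieces <- map(model_set$fits, function(f) {
    ages <- band_ages(f$band)
    occs <- if (model_set$use_occupation) wl_occupations() else "all"
    grid <- expand_grid(age = ages, year = model_set$years,
                        occupation = occs, origin = wl_states())
    # covariate levels unseen in this subsample are mapped to the nearest
    # seen level for prediction (labels are kept)
    newdata <- grid
    newdata$occupation <- ifelse(newdata$occupation %in% f$occupations,
                                 newdata$occupation, f$occupations[1])
    newdata$year <- vapply(newdata$year, function(y) {
      f$years[which.min(abs(f$years - y))]
    }, integer(1))

    probs <- matrix(0, nrow = nrow(grid), ncol = length(wl_all_states()),
                    dimnames = list(NULL, wl_all_states()))
    seen <- grid$origin %in% f$origins
    if (any(seen)) {
      if (is.null(f$model)) {
        probs[seen, f$destinations] <- 1
      } else {
        probs[seen, f$destinations] <-
          predict_probs(f$model, newdata[seen, , drop = FALSE], f$destinations)
      }
    }
    if (any(!seen)) {
      probs[cbind(which(!seen), match(grid$origin[!seen], wl_all_states()))] <- 1
    }
    bind_cols(tibble(sex = f$sex), grid, as_tibble(probs))
  })
  wide <- list_rbind(pieces)
  pset_long(enforce_boundaries(wide), provenance = "model-based")
}

#' Raw-frequency transition probabilities
#'
#' Tabulates observed transition frequencies per stratum cell with no
#' smoothing; an oracle for validating the model-based estimates. Cells with
#' zero exposure are absent (missing, not zero). With `complete = TRUE` the
#' grid is completed: zero-exposure cells become stay-in-state rows and the
#' boundary rules are enforced, yielding a set usable by the life-table
#' stage.
#'
#' @param records Transition records.
#' @param use_occupation Stratify by occupational category (otherwise pooled
#'   as `"all"`).
#' @param complete Complete the grid as described above.
#' @return A `transition_probs` tibble with provenance `"empirical"`.
#' @export
empirical_probability_set <- function(records, use_occupation = TRUE,
                                      complete = FALSE) {
  if (use_occupation) {
    records <- records[!is.na(records$occupation), ]
  } else {
    records$occupation <- "all"
  }
  freq <- records |>
    count(.data$sex, .data$occupation, .data$year, .data$age, .data$origin,
          .data$destination, name = "n") |>
    complete(destination = wl_all_states(),
             nesting(!!!rlang::syms(c("sex", "occupation", "year", "age", "origin"))),
             fill = list(n = 0L)) |>
    mutate(prob = .data$n / sum(.data$n),
           .by = c("sex", "occupation", "year", "age", "origin")) |>
    select(-"n")
  if (!complete) {
    return(transition_probs(freq, provenance = "empirical", partial = TRUE))
  }
  occs <- unique(freq$occupation)
  full <- expand_grid(sex = sort(unique(freq$sex)), occupation = occs,
                      year = sort(unique(freq$year)), age = AGE_MIN:AGE_MAX,
                      origin = wl_states())
  wide <- full |>
    left_join(pivot_wider(freq, names_from = "destination", values_from = "prob"),
              by = c("sex", "occupation", "year", "age", "origin"))
  unseen <- is.na(wide$dead)
  for (s in wl_all_states()) wide[[s]][unseen] <- 0
  stay <- cbind(which(unseen), match(wide$origin[unseen], wl_all_states()))
  m <- as.matrix(wide[, wl_all_states()])
  m[stay] <- 1
  wide[, wl_all_states()] <- as_tibble(m)
  pset_long(enforce_boundaries(wide), provenance = "empirical")
}
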