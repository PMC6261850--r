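# Ground-truth transition regimes for the synthetic register generator.
#
# The regime is parameterized in two stages. Death receives a Gompertz-type
# annual probability q(age) that is independent of the labor-force state;
# conditional on survival, the four living destinations split according to a
# multinomial logit whose linear predictors are additive in origin state,
# age curve, sex, occupational category, and a crisis shift on the
# employment destination from the crisis year onward. Additivity on the
# logit scale keeps the generating process inside the family of the
# estimation model, so parameter-recovery tests are genuine consistency
# checks rather than approximations.

#' Parameters of the ground-truth transition regime
#'
#' Returns a validated parameter block for [build_truth_regime()]. Defaults
#' describe a stylized southern-European labor market observed annually:
#' labor-market entry peaking in the mid-20s, high year-to-year employment
#' retention, a retirement hazard rising sharply after age 60, Gompertz-type
#' mortality, and a recession shock that lowers the employment destination
#' logit from `crisis_year` onward.
#'
#' @param years Calendar years `t` for which transitions `t -> t+1` exist.
#' @param entry_peak_age Age at which the entry-to-employment curve peaks.
#' @param entry_width Width (years) of the entry curve around its peak.
#' @param entry_level Approximate probability of moving inactive -> employed
#'   at the peak age (before renormalization against the other destinations).
#' @param employment_retention Approximate probability of staying employed
#'   at the peak age.
#' @param unemployment_persistence Approximate probability of staying
#'   unemployed year over year.
#' @param retirement_onset Age at which the retirement hazard turns on.
#' @param retirement_steepness Multiplier on the retirement logit ramp.
#' @param mortality_level Annual death probability at age 15 (both set to 0
#'   to obtain a deathless regime before the certain death at 99).
#' @param mortality_slope Gompertz log-slope of the death probability in age.
#' @param mortality_sex_ratio Female/male ratio of death probabilities.
#' @param crisis_year First calendar year of the downward employment shock.
#' @param crisis_magnitude Size of the shock on the employment logit
#'   (0 switches the shock off and makes the regime identical across years).
#' @param sex_gap Additive male advantage on the employment logit.
#' @param occupation_effects Named logit shifts of the employment destination
#'   by occupational category.
#' @return A list of class `wl_regime_params`.
#' @export
regime_params <- function(years = 2004:2012,
                          entry_peak_age = 25,
                          entry_width = 12,
                          entry_level = 0.35,
                          employment_retention = 0.9,
                          unemployment_persistence = 0.55,
                          retirement_onset = 61,
                          retirement_steepness = 1,
                          mortality_level = 3e-4,
                          mortality_slope = 0.09,
                          mortality_sex_ratio = 0.6,
                          crisis_year = 2008,
                          crisis_magnitude = 1.2,
                          sex_gap = 0.25,
                          occupation_effects = c(unskilled_manual = 0,
                                                 unskilled_nonmanual = 0.1,
                                                 skilled_manual = 0.05,
                                                 skilled_nonmanual = 0.3)) {
  p <- list(years = as.integer(years), entry_peak_age = entry_peak_age,
            entry_width = entry_width, entry_level = entry_level,
            employment_retention = employment_retention,
            unemployment_persistence = unemployment_persistence,
            retirement_onset = retirement_onset,
            retirement_steepness = retirement_steepness,
            mortality_level = mortality_level,
            mortality_slope = mortality_slope,
            mortality_sex_ratio = mortality_sex_ratio,
            crisis_year = crisis_year, crisis_magnitude = crisis_magnitude,
            sex_gap = sex_gap, occupation_effects = occupation_effects)
  for (nm in c("entry_level", "employment_retention", "unemployment_persistence")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1) {
      abort(sprintf("parameter '%s' must be a probability strictly inside (0, 1)", nm))
    }
  }
  if (p$mortality_level < 0 || p$mortality_level > 1) {
    abort("parameter 'mortality_level' must be a probability in [0, 1]")
  }
  if (p$mortality_slope < 0) abort("parameter 'mortality_slope' must be >= 0")
  if (p$crisis_magnitude < 0) abort("parameter 'crisis_magnitude' must be >= 0")
  if (!setequal(names(p$occupation_effects), wl_occupations())) {
    abort("occupation_effects must be named after all four occupational categories")
  }
  structure(p, class = "wl_regime_params")
}

# annual death probability, capped at 1
regime_mortality <- function(params, age, sex) {
  q <- params$mortality_level * exp(params$mortality_slope * (age - AGE_MIN))
  q <- q * ifelse(sex == "female", params$mortality_sex_ratio, 1)
  pmin(q, 1)
}

#' Build the ground-truth transition regime
#'
#' Materializes the regime described by [regime_params()] on the full grid
#' sex x occupational category x year x age 15-99 x origin x destination.
#' Boundary rules are enforced by construction: all destination rows sum to
#' one, death is certain at age 99, and at ages 80-98 all non-death mass
#' lies on the retired state.
#'
#' @param params A `wl_regime_params` block.
#' @return A `transition_probs` tibble with provenance `"ground-truth"` and
#'   the parameter block stored in the `"params"` attribute.
#' @export
build_truth_regime <- function(params = regime_params()) {
  if (!inherits(params, "wl_regime_params")) params <- do.call(regime_params, params)
  grid <- expand_grid(sex = wl_sexes(), occupation = wl_occupations(),
                      year = params$years, age = AGE_MIN:AGE_MAX,
                      origin = wl_states())
  age <- grid$age

  # employment destination: origin boost + entry parabola + strata shifts
  retention_boost <- qlogis(params$employment_retention) - qlogis(params$entry_level)
  b_e <- c(employed = retention_boost, unemployed = 0.4, inactive = 0, retired = -3)
  u_e <- qlogis(params$entry_level) -
    ((age - params$entry_peak_age) / params$entry_width)^2 +
    b_e[grid$origin] +
    ifelse(grid$sex == "male", params$sex_gap, 0) +
    params$occupation_effects[grid$occupation] -
    ifelse(grid$year >= params$crisis_year, params$crisis_magnitude, 0)

  # unemployment destination: persistence for the unemployed, job loss for
  # the employed, rare benefit receipt out of inactivity/retirement
  b_u <- c(employed = -1.6,
           unemployed = qlogis(params$unemployment_persistence) + 0.6,
           inactive = -2.5, retired = -5)
  u_u <- b_u[grid$origin] - 0.5 * ((age - 40) / 25)^2

  # retirement destination: smooth ramp after the onset age, strong
  # persistence once retired
  b_r <- c(employed = 0, unemployed = 0, inactive = 0, retired = 6)
  ramp <- 8 * params$retirement_steepness *
    plogis((age - params$retirement_onset - 3) / 1.5) - 6
  u_r <- b_r[grid$origin] + ramp

  expu <- cbind(employed = exp(u_e), unemployed = exp(u_u),
                inactive = 1, retired = exp(u_r))
  alive_share <- expu / rowSums(expu)
  q <- regime_mortality(params, age, grid$sex)

  wide <- grid
  for (s in wl_states()) wide[[s]] <- alive_share[, s] * (1 - q)
  wide$dead <- q
  out <- pset_long(enforce_boundaries(wide), provenance = "ground-truth")
  attr(out, "params") <- params
  out
}

#' Two-track segregated labor-market scenario
#'
#' Builds the stylized regime used to contrast incidence-based (Markov) and
#' prevalence-based (Sullivan) expectancies under a sudden entry shock.
#' Inactive individuals enter employment with probability `entry`, enter the
#' unemployment track with probability `(1 - entry) * takeup`, and otherwise
#' stay inactive; each track retains its members with probability
#' `retention`, with the leftover mass returning to inactivity. The entry
#' probability switches from `entry_before` to `entry_after` at
#' `shock_year`. Because track membership is sticky, period prevalences
#' react slowly to the switch while the transition rates react immediately.
#'
#' @param entry_before,entry_after Entry probabilities into the employment
#'   track before/from the shock year.
#' @param retention Year-over-year self-retention of both tracks; must leave
#'   an exit route (`retention < 1` unless mortality is positive).
#' @param takeup Probability that a failed entry lands on the unemployment
#'   track rather than staying inactive.
#' @param shock_year First year with `entry_after`.
#' @param years Calendar years covered.
#' @param mortality_level,mortality_slope Gompertz mortality as in
#'   [regime_params()] (sex-invariant here).
#' @return A `transition_probs` tibble (strata: both sexes, occupation
#'   `"all"`).
#' @export
build_segregated_market_scenario <- function(entry_before, entry_after,
                                             retention, takeup = 0.3,
                                             shock_year = 2008,
                                             years = 2004:2012,
                                             mortality_level = 3e-4,
                                             mortality_slope = 0.09) {
  for (v in c(entry_before, entry_after, retention, takeup)) {
    if (!is.numeric(v) || v < 0 || v > 1) abort("all scenario arguments must be probabilities")
  }
  if (retention >= 1 && mortality_level == 0) {
    abort("retention >= 1 with no mortality leaves no exit from the tracks")
  }
  grid <- expand_grid(sex = wl_sexes(), occupation = "all",
                      year = as.integer(years), age = AGE_MIN:AGE_MAX,
                      origin = wl_states())
  entry <- ifelse(grid$year >= shock_year, entry_after, entry_before)
  q <- pmin(mortality_level * exp(mortality_slope * (grid$age - AGE_MIN)), 1)

  p_e <- p_u <- p_i <- p_r <- numeric(nrow(grid))
  from <- grid$origin
  p_e[from == "inactive"] <- entry[from == "inactive"]
  p_u[from == "inactive"] <- (1 - entry[from == "inactive"]) * takeup
  p_i[from == "inactive"] <- (1 - entry[from == "inactive"]) * (1 - takeup)
  p_e[from == "employed"] <- retention
  p_i[from == "employed"] <- 1 - retention
  p_u[from == "unemployed"] <- retention
  p_i[from == "unemployed"] <- 1 - retention
  p_r[from == "retired"] <- 1

  wide <- grid
  wide$employed <- p_e * (1 - q)
  wide$unemployed <- p_u * (1 - q)
  wide$inactive <- p_i * (1 - q)
  wide$retired <- p_r * (1 - q)
  wide$dead <- q
  pset_long(enforce_boundaries(wide), provenance = "ground-truth")
}
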