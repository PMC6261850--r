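# End-to-end orchestration: simulate (optional) -> ingest -> fit -> adjust
# (optional) -> life table -> Sullivan -> comparison, with CSV outputs and a
# reproducibility manifest.

#' Assemble a pipeline configuration
#'
#' @param ... Overrides of the default configuration, or a single list.
#'   Fields: `seed`, `out_dir`, `simulate` (arguments of
#'   [synthetic_config()]), `regime` (overrides of [regime_params()]),
#'   `spells_path`/`deaths_path` (read register extracts instead of
#'   simulating), `use_occupation`, `total_population` (additionally fit an
#'   occupation-free model set for the total-population outputs),
#'   `adjust`, `reference` (`"regime"`, or named list of life-table paths by
#'   sex), `compare_periods` (two transition years for the change
#'   decomposition), `sullivan`, `start_age`, `init`,
#'   `write_probabilities`.
#' @param path Optional YAML or JSON file whose keys are applied before
#'   `...`. In YAML, quote the key `"n"`: YAML 1.1 scans a bare `n` as a
#'   boolean.
#' @return A list of class `wl_pipeline_config`.
#' @export
pipeline_config <- function(..., path = NULL) {
  defaults <- list(
    seed = 1L,
    out_dir = "worklife-output",
    simulate = list(n = 20000),
    regime = list(),
    spells_path = NULL,
    deaths_path = NULL,
    use_occupation = TRUE,
    total_population = TRUE,
    adjust = TRUE,
    reference = "regime",
    compare_periods = c(2006L, 2008L),
    sullivan = TRUE,
    start_age = AGE_MIN,
    init = c(inactive = 1),
    write_probabilities = TRUE)
  cfg <- defaults
  if (!is.null(path)) {
    file_cfg <- if (grepl("\\.ya?ml$", path)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    cfg <- utils::modifyList(cfg, file_cfg)
  }
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.list(dots[[1]])) dots <- dots[[1]]
  cfg <- utils::modifyList(cfg, dots)
  cfg$init <- unlist(cfg$init)
  structure(cfg, class = "wl_pipeline_config")
}

stage_message <- function(stage, ...) {
  inform(paste0("[", stage, "] ", sprintf(...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> ingest -> fit -> adjust (optional) ->
#' life table -> Sullivan -> comparison, writes all tabular outputs as CSV
#' under `config$out_dir` together with a run manifest (configuration hash,
#' seed, package and R versions), and returns the artifact bundle. Runs are
#' idempotent: the same configuration and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()] (or a list / file path accepted by
#'   it).
#' @return A list of class `wl_bundle` with the tables, the manifest and the
#'   output paths, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- pipeline_config(path = config)
  if (!inherits(config, "wl_pipeline_config")) config <- pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  regime <- NULL
  if (is.null(config$spells_path) || identical(config$reference, "regime")) {
    regime <- run_stage("simulate", build_truth_regime(
      do.call(regime_params, config$regime)))
  }

  if (is.null(config$spells_path)) {
    sim_cfg <- do.call(synthetic_config, utils::modifyList(
      list(seed = config$seed), as.list(config$simulate)))
    stage_message("simulate", "drawing %d trajectories (seed %d)", sim_cfg$n, sim_cfg$seed)
    spells <- run_stage("simulate", simulate_trajectories(regime, sim_cfg))
  } else {
    stage_message("simulate", "reading spells from %s", config$spells_path)
    spells <- run_stage("simulate", read_spells(config$spells_path, config$deaths_path))
  }

  stage_message("ingest", "building person-years and transition records")
  person_years <- run_stage("ingest", build_person_years(spells))
  records <- run_stage("ingest", build_transition_records(
    person_years, deaths = attr(spells, "deaths")))

  stage_message("fit", "fitting subsample multinomial models (occupation: %s)",
                config$use_occupation)
  model_set <- run_stage("fit", fit_transition_models(
    records, use_occupation = config$use_occupation))
  pset <- run_stage("fit", predict_probability_set(model_set))
  pset_total <- if (config$use_occupation && config$total_population) {
    stage_message("fit", "fitting the occupation-free (total population) models")
    run_stage("fit", predict_probability_set(
      fit_transition_models(records, use_occupation = FALSE)))
  } else if (!config$use_occupation) {
    pset
  } else {
    NULL
  }

  reference <- NULL
  if (isTRUE(config$adjust) || isTRUE(config$sullivan)) {
    reference <- run_stage("adjust", resolve_reference(config, regime))
  }
  adjustment <- NULL
  if (isTRUE(config$adjust)) {
    stage_message("adjust", "aligning mortality with the reference life tables")
    pset <- run_stage("adjust", adjust_probability_set(
      pset, reference, init = config$init, start_age = config$start_age))
    adjustment <- attr(pset, "adjustment")
    if (!is.null(pset_total) && config$use_occupation) {
      pset_total <- run_stage("adjust", adjust_probability_set(
        pset_total, reference, init = config$init, start_age = config$start_age))
    } else if (!config$use_occupation) {
      pset_total <- pset
    }
  }

  stage_message("lifetable", "computing state expectancies and decompositions")
  expectancies <- run_stage("lifetable", expectancy_table(
    pset, start_age = config$start_age, init = config$init))
  expectancies_total <- if (!is.null(pset_total)) {
    run_stage("lifetable", expectancy_table(
      pset_total, start_age = config$start_age, init = config$init))
  } else {
    NULL
  }

  decomposition <- run_stage("lifetable", decomposition_tables(
    pset, config$start_age, config$init, config$compare_periods))

  comparison <- NULL
  if (isTRUE(config$sullivan)) {
    stage_message("sullivan", "prevalence schedules and AWLE comparison")
    comparison <- run_stage("sullivan", sullivan_comparison(
      person_years, expectancies_total %||% expectancies, reference,
      start_age = config$start_age))
  }

  manifest <- list(config_hash = hash(unclass(config)),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("worklife")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."))

  bundle <- structure(list(
    config = config, manifest = manifest,
    person_years = person_years, records_n = nrow(records),
    probability_set = pset,
    expectancies = expectancies, expectancies_total = expectancies_total,
    decomposition = decomposition$bands,
    change_decomposition = decomposition$change,
    comparison = comparison, adjustment = adjustment,
    out_dir = out_dir), class = "wl_bundle")

  write_bundle(bundle, write_probabilities = isTRUE(config$write_probabilities))
  invisible(bundle)
}

# mixture-weighted aggregate mortality of the truth regime, per sex, as an
# annual-convention reference life table
resolve_reference <- function(config, regime) {
  if (!identical(config$reference, "regime")) {
    return(map(config$reference, read_reference_lifetable))
  }
  if (is.null(regime)) abort("reference = 'regime' requires a simulated regime")
  year <- min(regime$year)
  occs <- unique(regime$occupation)
  w <- if (identical(occs, "all")) c(all = 1) else {
    cfg_occ <- config$simulate$occupation_probs %||%
      synthetic_config()$occupation_probs
    cfg_occ[occs]
  }
  sexes <- unique(regime$sex)
  ref <- map(setNames(sexes, sexes), function(sx) {
    q <- 0
    for (o in occs) {
      q <- q + w[[o]] * implied_mortality(regime, sx, o, year,
                                          start_age = config$start_age,
                                          init = config$init)$qhat
    }
    make_lifetable(q / sum(unlist(w)), age = config$start_age:AGE_MAX,
                   convention = "annual")
  })
  ref
}

decomposition_tables <- function(pset, start_age, init, compare_periods) {
  strata <- pset_strata(pset)
  bands_list <- map(seq_len(nrow(strata)), function(i) {
    occ <- state_occupancy(pset, strata$sex[i], strata$occupation[i],
                           strata$year[i], start_age, init)
    decompose_by_age_band(occ, state = "employed") |>
      mutate(sex = strata$sex[i], occupation = strata$occupation[i],
             period = period_label(strata$year[i]), .before = 1)
  })
  change_list <- list()
  if (!is.null(compare_periods) && length(compare_periods) == 2 &&
      all(compare_periods %in% strata$year)) {
    pairs <- distinct(strata, .data$sex, .data$occupation)
    change_list <- map(seq_len(nrow(pairs)), function(i) {
      o1 <- state_occupancy(pset, pairs$sex[i], pairs$occupation[i],
                            compare_periods[1], start_age, init)
      o2 <- state_occupancy(pset, pairs$sex[i], pairs$occupation[i],
                            compare_periods[2], start_age, init)
      change_decomposition(o1, o2, state = "employed") |>
        mutate(sex = pairs$sex[i], occupation = pairs$occupation[i],
               from = period_label(compare_periods[1]),
               to = period_label(compare_periods[2]), .before = 1)
    })
  }
  list(bands = list_rbind(bands_list),
       change = if (length(change_list)) list_rbind(change_list) else NULL)
}

sullivan_comparison <- function(person_years, expectancies, reference,
                                start_age = AGE_MIN) {
  markov <- expectancies |>
    pivot_longer(all_of(c(wl_states(), "total")),
                 names_to = "state", values_to = "years") |>
    summarise(awle = sum(.data$years[.data$state %in% c("employed", "unemployed")]),
              .by = c("sex", "period")) |>
    mutate(year = as.integer(sub("/.*$", "", .data$period)))
  out <- map(unique(markov$sex), function(sx) {
    ref <- if (inherits(reference, "wl_lifetable")) reference else reference[[sx]]
    years <- sort(unique(person_years$year[person_years$sex == sx]))
    sull <- tibble(year = years,
                   awle = vapply(years, function(y) {
                     d <- prevalence_schedule(person_years, sex = sx, year = y)
                     sullivan_expectancy(ref, d, state = c("employed", "unemployed"),
                                         start_age = start_age)
                   }, numeric(1)))
    compare_markov_sullivan(markov[markov$sex == sx, ], sull) |>
      mutate(sex = sx, .before = 1)
  })
  list_rbind(out)
}

write_bundle <- function(bundle, write_probabilities = TRUE) {
  out <- bundle$out_dir
  w <- function(x, name) {
    if (is.null(x)) return(invisible(NULL))
    readr::write_csv(as_tibble(x), file.path(out, name))
  }
  w(bundle$expectancies, "expectancies.csv")
  w(bundle$expectancies_total, "expectancies_total.csv")
  w(bundle$decomposition, "decomposition.csv")
  w(bundle$change_decomposition, "change_decomposition.csv")
  w(bundle$comparison, "awle_comparison.csv")
  if (!is.null(bundle$adjustment)) {
    w(bundle$adjustment$report, "adjustment_report.csv")
    w(bundle$adjustment$scale_factors, "adjustment_scale_factors.csv")
  }
  if (write_probabilities) w(bundle$probability_set, "transition_probabilities.csv")
  jsonlite::write_json(bundle$manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Render a plain-text report of a pipeline run
#'
#' One Markdown document with the expectancy tables per period and stratum
#' (rounded to one decimal), the age-band decompositions, the change
#' decomposition, and the Markov-vs-Sullivan AWLE comparison. Missing
#' sections are listed as absent rather than failing.
#'
#' @param bundle A [run_pipeline()] bundle.
#' @param path Output file (default `report.md` in the bundle's output
#'   directory).
#' @return The path, invisibly.
#' @export
render_report <- function(bundle, path = file.path(bundle$out_dir, "report.md")) {
  round_df <- function(df) mutate(df, across(where(is.numeric) & !any_of("year"),
                                             ~ round(.x, 1)))
  section <- function(title, x) {
    if (is.null(x)) {
      c(paste("##", title), "", "_Not available in this run._", "")
    } else {
      c(paste("##", title), "", md_table(round_df(as_tibble(x))), "")
    }
  }
  lines <- c("# Working life expectancy report", "",
             sprintf("Seed %s | config hash %s", bundle$manifest$seed,
                     bundle$manifest$config_hash), "",
             section("State expectancies by stratum and period", bundle$expectancies),
             section("Total-population state expectancies", bundle$expectancies_total),
             section("Age-band decomposition of WLE", bundle$decomposition),
             section("Age-band decomposition of WLE change", bundle$change_decomposition),
             section("AWLE: Markov vs Sullivan", bundle$comparison))
  writeLines(lines, path)
  invisible(path)
}

md_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
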