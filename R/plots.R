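# ggplot2 displays for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.wl_occupancy <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$age, y = .data$occupancy,
                               fill = factor(.data$state, levels = wl_states()))) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Age", y = "Probability alive and in state", fill = "State") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.wl_prevalence <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$age, y = .data$prevalence,
                               colour = factor(.data$state, levels = wl_states()))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age", y = "Prevalence", colour = "State") +
    ggplot2::theme_minimal()
}

#' Plot a state-expectancy series across periods
#'
#' @param expectancies A wide expectancy table (from [expectancy_table()]).
#' @param state Column to plot (default the working life expectancy).
#' @return A ggplot object.
#' @export
plot_expectancy_series <- function(expectancies, state = "employed") {
  ggplot2::ggplot(expectancies,
                  ggplot2::aes(x = .data$period, y = .data[[state]],
                               colour = .data$sex,
                               group = interaction(.data$sex, .data$occupation))) +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$occupation)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Period", y = sprintf("Years %s (from age 15)", state)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an age-band decomposition
#'
#' @param decomposition A `wl_decomposition` tibble (contributions or
#'   changes).
#' @return A ggplot object.
#' @export
plot_decomposition <- function(decomposition) {
  value <- if ("change" %in% names(decomposition)) "change" else "years"
  ggplot2::ggplot(decomposition,
                  ggplot2::aes(x = factor(.data$band, levels = unique(.data$band)),
                               y = .data[[value]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Age band", y = sprintf("Contribution (%s)", value)) +
    ggplot2::theme_minimal()
}

#' Plot the Markov-vs-Sullivan AWLE comparison
#'
#' @param comparison Output of [compare_markov_sullivan()] (optionally with a
#'   `sex` column).
#' @return A ggplot object.
#' @export
plot_awle_comparison <- function(comparison) {
  long <- pivot_longer(as_tibble(comparison), c("markov", "sullivan"),
                       names_to = "estimator", values_to = "awle")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$awle,
                                          colour = .data$estimator)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Year", y = "AWLE (years)", colour = "Estimator") +
    ggplot2::theme_minimal()
  if ("sex" %in% names(comparison)) p <- p + ggplot2::facet_wrap(~sex)
  p
}
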