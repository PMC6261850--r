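# Bundled example data.

#' Published working-life expectancy table for Spain, 2004-2013
#'
#' Remaining life expectancy at age 15 (years) spent in employment,
#' unemployment, inactivity and retirement for Spanish males and females by
#' two-year transition period, as published from the national social
#' security register sample. Used in worked examples and for arithmetic
#' checks of the additivity identity (the four state expectancies sum to the
#' total remaining life expectancy); note that per-cell rounding to one
#' decimal makes some printed rows internally inconsistent by a few tenths
#' of a year.
#'
#' @return Tibble with columns `sex`, `period`, `employed`, `unemployed`,
#'   `inactive`, `retired`, `total`.
#' @export
spain_wle_table <- function() {
  path <- system.file("extdata", "spain_wle_2004_2013.csv", package = "worklife")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Path to the bundled synthetic reference life table
#'
#' A small period life table in the whitespace-delimited layout of the usual
#' mortality-database downloads (columns `Age`, `qx`, `lx`, `Lx`, open age
#' group `110+`). The table is synthetic — generated from a smooth
#' Gompertz-type schedule — and serves to exercise
#' [read_reference_lifetable()]; it is not observed data.
#'
#' @return File path.
#' @export
synthetic_lifetable_path <- function() {
  system.file("extdata", "synthetic_reference_lifetable.txt", package = "worklife")
}
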