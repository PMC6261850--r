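# Period reference life tables: construction from death probabilities,
# reading of external (HMD-style) tables, and remaining life expectancy
# under either person-year convention.

#' Build a period life table from death probabilities
#'
#' @param qx Death probabilities by single year of age.
#' @param age Ages (defaults to 15, 16, ...); the table is truncated at 99
#'   and the final death probability set to 1.
#' @param radix Survivors at the first age.
#' @param convention Person-year convention for `Lx`:
#'   `"midpoint"` assumes deaths occur mid-interval (`a_x = 0.5`,
#'   the usual period life-table convention, used for external tables);
#'   `"annual"` counts one full year for everyone alive at the start of the
#'   age interval (`Lx = lx`), matching the whole-year state accounting of
#'   the multistate life table — use it for any table derived from, or
#'   compared against, the Markov chain.
#' @return Tibble of class `wl_lifetable` with columns `age`, `qx`, `lx`,
#'   `Lx`, `ex`.
#' @export
make_lifetable <- function(qx, age = seq(AGE_MIN, length.out = length(qx)),
                           radix = 1e5,
                           convention = c("midpoint", "annual")) {
  convention <- match.arg(convention)
  if (any(qx < 0 | qx > 1)) abort("death probabilities must lie in [0, 1]")
  if (any(diff(age) != 1)) abort("ages must be consecutive single years")
  keep <- age <= AGE_MAX
  age <- age[keep]
  qx <- qx[keep]
  qx[length(qx)] <- 1
  lx <- radix * cumprod(c(1, 1 - qx[-length(qx)]))
  dx <- lx * qx
  Lx <- if (convention == "midpoint") lx - 0.5 * dx else lx
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  out <- tibble(age = as.integer(age), qx = qx, lx = lx, Lx = Lx, ex = ex)
  attr(out, "radix") <- radix
  attr(out, "convention") <- convention
  class(out) <- c("wl_lifetable", class(tibble()))
  out
}

#' Read an external period reference life table
#'
#' Accepts delimited text (comma- or whitespace-separated) in the usual
#' period life-table layout with at least `Age` and `qx` columns; `lx` and
#' `Lx` are kept when present and consistent, and reconstructed otherwise
#' (radix 100,000, deaths at mid-interval). Open age groups such as `"110+"`
#' are parsed; the table is restricted to ages 15-99 and the final death
#' probability is set to 1.
#'
#' @param path File path.
#' @param min_age,max_age Age range retained.
#' @return A `wl_lifetable` tibble (midpoint convention).
#' @export
read_reference_lifetable <- function(path, min_age = AGE_MIN, max_age = AGE_MAX) {
  first <- readLines(path, n = 1L)
  raw <- if (grepl(",", first)) {
    readr::read_csv(path, show_col_types = FALSE)
  } else {
    readr::read_table(path, show_col_types = FALSE)
  }
  # 'lx' and 'Lx' are distinct columns; resolve names case-sensitively
  nm <- names(raw)
  lower <- tolower(nm)
  pick <- function(target, exact = NULL) {
    hits <- which(lower == target)
    if (length(hits) > 1L && !is.null(exact)) hits <- which(nm == exact)
    if (length(hits) == 0L) NA_integer_ else hits[1]
  }
  i_age <- pick("age")
  i_qx <- pick("qx")
  if (is.na(i_age) || is.na(i_qx)) {
    abort("a reference life table needs at least 'Age' and 'qx' columns")
  }
  i_lx <- pick("lx", exact = "lx")
  i_Lx <- if (sum(lower == "lx") > 1L) which(nm == "Lx")[1] else NA_integer_
  if (sum(lower == "lx") == 1L && nm[lower == "lx"] == "Lx") {
    i_Lx <- which(nm == "Lx")[1]
    i_lx <- NA_integer_
  }
  out_nm <- c("age", "qx", "lx", "Lx")
  idx <- c(i_age, i_qx, i_lx, i_Lx)
  raw <- setNames(raw[, idx[!is.na(idx)], drop = FALSE], out_nm[!is.na(idx)])
  raw$age <- as.integer(sub("\\+$", "", as.character(raw$age)))
  bad_q <- which(is.na(raw$qx) | raw$qx < 0 | raw$qx > 1)
  if (length(bad_q) > 0) {
    abort(sprintf("invalid death probability in row %d", bad_q[1]))
  }
  if (is.unsorted(raw$age, strictly = TRUE)) {
    abort(sprintf("ages must be strictly increasing (violated at row %d)",
                  which(diff(raw$age) <= 0)[1] + 1L))
  }
  raw <- raw[raw$age >= min_age & raw$age <= max_age, ]
  if (any(diff(raw$age) != 1)) abort("life-table ages must be consecutive")
  qx <- raw$qx
  qx[length(qx)] <- 1

  radix <- 1e5
  if ("lx" %in% names(raw)) {
    lx <- raw$lx
    pred <- lx[-length(lx)] * (1 - qx[-length(qx)])
    if (any(abs(lx[-1] - pred) > 1e-5 * lx[1] + 1e-8)) {
      bad <- which(abs(lx[-1] - pred) > 1e-5 * lx[1] + 1e-8)[1] + 1L
      abort(sprintf("lx is inconsistent with qx at row %d", bad))
    }
    radix <- lx[1]
  } else {
    lx <- radix * cumprod(c(1, 1 - qx[-length(qx)]))
  }
  Lx <- if ("Lx" %in% names(raw)) raw$Lx else lx - 0.5 * lx * qx
  Tx <- rev(cumsum(rev(Lx)))
  out <- tibble(age = raw$age, qx = qx, lx = lx, Lx = Lx,
                ex = ifelse(lx > 0, Tx / lx, 0))
  attr(out, "radix") <- radix
  attr(out, "convention") <- "midpoint"
  class(out) <- c("wl_lifetable", class(tibble()))
  out
}

#' Remaining life expectancy of a life table at a given age
#'
#' @param lifetable A `wl_lifetable`.
#' @param age Start age.
#' @return Remaining expectancy in years (under the table's person-year
#'   convention).
#' @export
lifetable_expectancy <- function(lifetable, age = AGE_MIN) {
  i <- match(age, lifetable$age)
  if (is.na(i)) abort(sprintf("age %s is not on the life table", age))
  lifetable$ex[i]
}
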