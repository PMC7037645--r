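#' LMS growth-reference z-scores and percentiles
#'
#' The LMS method summarizes an age- and sex-specific reference
#' distribution by a Box-Cox power `L`, median `M` and coefficient of
#' variation `S`. A measurement `x` maps to
#' `z = ((x/M)^L - 1) / (L * S)` for `L != 0` and `z = log(x/M) / S` for
#' `L = 0`; the percentile is `100 * pnorm(z)`.
#'
#' @param x measurement value (> 0), e.g. BMI in kg/m^2.
#' @param l,m,s LMS parameters (`m > 0`, `s > 0`); vectors are recycled.
#' @return `lms_zscore()` returns the z-score; `lms_percentile()` the
#'   percentile in (0, 100).
#' @export
#' @examples
#' lms_zscore(20, l = 1, m = 20, s = 0.1) # 0 at the median
#' lms_percentile(22, l = -1.5, m = 18, s = 0.12)
lms_zscore <- function(x, l, m, s) {
  if (any(!is.finite(x)) || any(x <= 0)) stop_input("`x` must be positive")
  if (any(m <= 0) || any(s <= 0)) stop_input("LMS parameters need m > 0, s > 0")
  ifelse(l == 0, log(x / m) / s, ((x / m)^l - 1) / (l * s))
}

#' @rdname lms_zscore
#' @export
lms_percentile <- function(x, l, m, s) {
  100 * pnorm(lms_zscore(x, l, m, s))
}

#' Read an LMS reference table
#'
#' Expects CSV columns `sex, agemos, L, M, S` (age in months). A small
#' synthetic BMI-for-age fixture ships with the package for testing and
#' examples; substitute an official growth-chart table for real use.
#'
#' @param path CSV path; default is the packaged synthetic fixture.
#' @return A data frame sorted by sex then age.
#' @export
read_lms_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lms_bmi_synthetic.csv",
                        package = "kidfitr", mustWork = TRUE)
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sex", "agemos", "L", "M", "S")
  if (!all(needed %in% names(tab))) {
    stop_input("LMS CSV must have columns sex, agemos, L, M, S")
  }
  if (any(tab$M <= 0) || any(tab$S <= 0)) {
    stop_input("LMS table needs M > 0 and S > 0 in every row")
  }
  tab[order(tab$sex, tab$agemos), , drop = FALSE]
}

#' Interpolate LMS parameters at an exact age
#'
#' Linear interpolation of each of L, M and S in age between the two
#' adjacent reference rows for the child's sex; ages outside the table's
#' range use the nearest boundary row.
#'
#' @param table an LMS reference table ([read_lms_table()]).
#' @param sex `"female"` / `"male"`.
#' @param agemos age in months.
#' @return A one-row data frame with columns `L`, `M`, `S`.
#' @export
lms_lookup <- function(table, sex, agemos) {
  rows <- table[table$sex == sex, , drop = FALSE]
  if (nrow(rows) == 0) stop_input(sprintf("no LMS rows for sex `%s`", sex))
  if (nrow(rows) == 1) return(rows[, c("L", "M", "S")])
  a <- clamp(agemos, min(rows$agemos), max(rows$agemos))
  data.frame(
    L = stats::approx(rows$agemos, rows$L, xout = a, ties = "ordered")$y,
    M = stats::approx(rows$agemos, rows$M, xout = a, ties = "ordered")$y,
    S = stats::approx(rows$agemos, rows$S, xout = a, ties = "ordered")$y
  )
}

#' BMI percentile for one child via an LMS reference
#'
#' Convenience wrapper: looks up (and age-interpolates) the LMS row for
#' the child's sex and age, then converts the BMI value to a percentile.
#'
#' @param bmi BMI, kg/m^2.
#' @param sex `"female"` / `"male"`.
#' @param agemos age in months.
#' @param table an LMS reference table ([read_lms_table()]).
#' @return Percentile in (0, 100).
#' @export
bmi_percentile_lms <- function(bmi, sex, agemos, table = read_lms_table()) {
  row <- lms_lookup(table, sex, agemos)
  lms_percentile(bmi, row$L, row$M, row$S)
}
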