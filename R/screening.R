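#' The KidFit screening rule
#'
#' A child is KidFit positive when the SAMS time is at or above
#' `sams_cutoff` (default 5.43 s) and/or the MSTP-predicted VO2max is at
#' or below the sex-specific cut-off (default 34.9 mL/kg/min for girls,
#' 45.1 for boys). Both boundaries are inclusive.
#'
#' The MSTP-to-VO2max prediction equation is a configuration input: the
#' validated equation is published separately and is not hard-coded here.
#' [default_vo2_coefficients()] supplies a synthetic moment-matched
#' stand-in (slope = SD ratio of predicted VO2max to MSTP score, intercept
#' anchored so the mean MSTP score of 21.83 laps maps to the mean
#' predicted VO2peak of 43.63 mL/kg/min); substitute the published
#' coefficients for real screening work.
#'
#' @param sams_cutoff SAMS positivity threshold, seconds (> 0).
#' @param vo2_cutoff_female,vo2_cutoff_male reduced-CRF thresholds,
#'   mL/kg/min (> 0).
#' @param vo2_prediction_coefficients named numeric vector (or list) of
#'   linear-predictor coefficients. Must contain `intercept`; remaining
#'   names are matched against `mstp` and any supplied covariates.
#' @return An object of class `screening_rule`.
#' @export
#' @examples
#' rule <- screening_rule()
#' classify_kidfit(6.0, 50, "male", rule)
screening_rule <- function(sams_cutoff = 5.43,
                           vo2_cutoff_female = 34.9,
                           vo2_cutoff_male = 45.1,
                           vo2_prediction_coefficients = default_vo2_coefficients()) {
  check_scalar_number(sams_cutoff, "sams_cutoff", lower = 1e-12, config = TRUE)
  check_scalar_number(vo2_cutoff_female, "vo2_cutoff_female", lower = 1e-12,
                      config = TRUE)
  check_scalar_number(vo2_cutoff_male, "vo2_cutoff_male", lower = 1e-12,
                      config = TRUE)
  coefs <- vo2_prediction_coefficients
  if (!is.null(coefs)) {
    coefs <- unlist(coefs)
    if (length(coefs) == 0 || is.null(names(coefs)) || any(names(coefs) == "")) {
      stop_config("`vo2_prediction_coefficients` must be a non-empty named numeric vector",
                  field = "vo2_prediction_coefficients")
    }
  }
  structure(
    list(sams_cutoff = sams_cutoff,
         vo2_cutoff_female = vo2_cutoff_female,
         vo2_cutoff_male = vo2_cutoff_male,
         vo2_prediction_coefficients = coefs),
    class = "screening_rule"
  )
}

#' @rdname screening_rule
#' @export
default_vo2_coefficients <- function() {
  slope <- 9.16 / 2.93
  c(intercept = 43.63 - slope * 21.83, mstp = slope)
}

#' @export
print.screening_rule <- function(x, ...) {
  cat("<screening_rule>\n")
  cat(sprintf("  SAMS positive at >= %.2f s\n", x$sams_cutoff))
  cat(sprintf("  reduced CRF at predicted VO2max <= %.1f (girls) / %.1f (boys) mL/kg/min\n",
              x$vo2_cutoff_female, x$vo2_cutoff_male))
  if (is.null(x$vo2_prediction_coefficients)) {
    cat("  VO2max prediction coefficients: <not set>\n")
  } else {
    cat("  VO2max prediction: ",
        paste(sprintf("%s=%.4g", names(x$vo2_prediction_coefficients),
                      x$vo2_prediction_coefficients), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Score the Modified Shuttle Test-Paeds
#'
#' One point per bean bag returned to the tray in 3 minutes, plus half a
#' point for a final bag picked up but not yet returned.
#'
#' @param bags_returned nonnegative integer count of bags returned.
#' @param extra_bag_in_hand logical; was a further bag in hand at the
#'   whistle?
#' @return Score in laps, a multiple of 0.5.
#' @export
#' @examples
#' mstp_score(21, TRUE) # 21.5
mstp_score <- function(bags_returned, extra_bag_in_hand = FALSE) {
  if (any(!is.finite(bags_returned)) || any(bags_returned < 0) ||
      any(bags_returned != round(bags_returned))) {
    stop_input("`bags_returned` must be a nonnegative whole number")
  }
  bags_returned + 0.5 * as.numeric(extra_bag_in_hand)
}

#' Predict VO2max from an MSTP score
#'
#' Evaluates the linear predictor defined by
#' `rule$vo2_prediction_coefficients` at the given MSTP score and optional
#' covariates. Coefficient names select predictors: `intercept` is the
#' constant, `mstp` multiplies the MSTP score, any other name must be
#' present in `covariates`.
#'
#' @param mstp MSTP score, laps.
#' @param rule a [screening_rule()] carrying prediction coefficients.
#' @param covariates optional named list / data frame of extra predictors
#'   (e.g. `age`, `sex01`).
#' @return Predicted VO2max, mL/kg/min.
#' @export
predict_vo2max <- function(mstp, rule = screening_rule(), covariates = NULL) {
  coefs <- rule$vo2_prediction_coefficients
  if (is.null(coefs) || length(coefs) == 0) {
    stop_config(paste(
      "no VO2max prediction coefficients configured:",
      "supply the published MSTP prediction equation (or a custom one) via",
      "`screening_rule(vo2_prediction_coefficients = ...)`"),
      field = "vo2_prediction_coefficients")
  }
  out <- rep(0, length(mstp))
  for (nm in names(coefs)) {
    out <- out + switch(nm,
      intercept = coefs[[nm]],
      mstp = coefs[[nm]] * mstp,
      {
        if (is.null(covariates) || is.null(covariates[[nm]])) {
          stop_input(sprintf("coefficient `%s` has no matching covariate", nm))
        }
        coefs[[nm]] * covariates[[nm]]
      })
  }
  as.numeric(out)
}

#' Apply the KidFit positivity rule
#'
#' Flags each child on the two screen components and combines them:
#' `sams_flag` when `sams_time >= rule$sams_cutoff`, `crf_flag` when the
#' predicted VO2max is at or below the sex-specific cut-off, and
#' `overall = "positive"` when either flag is raised.
#'
#' @param sams_time SAMS time, seconds (> 0).
#' @param predicted_vo2 predicted VO2max, mL/kg/min (finite).
#' @param sex `"female"` / `"male"` (recycled if length 1).
#' @param rule a [screening_rule()].
#' @return A data frame with columns `sams_flag`, `crf_flag`, `overall`
#'   (factor `positive`/`negative`).
#' @export
#' @examples
#' classify_kidfit(c(6, 5.43, 4), c(50, 60, 34.9),
#'                 c("male", "female", "female"))
classify_kidfit <- function(sams_time, predicted_vo2, sex,
                            rule = screening_rule()) {
  n <- max(length(sams_time), length(predicted_vo2), length(sex))
  sams_time <- rep_len(sams_time, n)
  predicted_vo2 <- rep_len(predicted_vo2, n)
  sex <- rep_len(as.character(sex), n)
  if (any(!is.finite(sams_time)) || any(sams_time <= 0)) {
    stop_input("`sams_time` must be finite and positive")
  }
  if (any(!is.finite(predicted_vo2))) {
    stop_input("`predicted_vo2` must be finite")
  }
  asym <- rule$vo2_cutoff_female != rule$vo2_cutoff_male
  if (any(is.na(sex) | !(sex %in% c("female", "male"))) && asym) {
    stop_input("`sex` must be \"female\" or \"male\" when the CRF cut-offs differ by sex")
  }
  cutoff <- ifelse(sex == "male", rule$vo2_cutoff_male, rule$vo2_cutoff_female)
  sams_flag <- sams_time >= rule$sams_cutoff
  crf_flag <- predicted_vo2 <= cutoff
  data.frame(
    sams_flag = sams_flag,
    crf_flag = crf_flag,
    overall = factor(ifelse(sams_flag | crf_flag, "positive", "negative"),
                     levels = c("negative", "positive"))
  )
}

#' Cardiorespiratory-fitness band classification
#'
#' Assigns a VO2max value to one of six aerobic-fitness bands (very poor,
#' poor, fair, good, excellent, superior) using sex-specific band edges,
#' and flags the reduced-CRF bands (very poor / poor / fair). The shipped
#' default table ([crf_band_table()]) places the fair/good boundary at the
#' normative reduced-CRF cut-offs (34.9 mL/kg/min girls, 45.1 boys); the
#' remaining edges are representative adolescent reference values and the
#' table is editable (CSV columns `sex, band, upper`).
#'
#' @param vo2 VO2max, mL/kg/min (> 0).
#' @param sex `"female"` / `"male"`.
#' @param band_table band-edge table as returned by [crf_band_table()].
#' @return A data frame with columns `band` (ordered factor) and
#'   `reduced` (logical).
#' @export
#' @examples
#' crf_band(41.32, "female") # excellent, not reduced
crf_band <- function(vo2, sex, band_table = crf_band_table()) {
  n <- max(length(vo2), length(sex))
  vo2 <- rep_len(vo2, n)
  sex <- rep_len(as.character(sex), n)
  if (any(!is.na(vo2) & (!is.finite(vo2) | vo2 <= 0))) {
    stop_input("`vo2` must be positive")
  }
  bands <- band_levels()
  band <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.na(vo2[i])) next
    edges <- band_table[band_table$sex == sex[i], , drop = FALSE]
    edges <- edges[match(bands, edges$band), , drop = FALSE]
    band[i] <- bands[which(vo2[i] <= edges$upper)[1]]
  }
  reduced <- band %in% c("very poor", "poor", "fair")
  reduced[is.na(band)] <- NA
  data.frame(band = factor(band, levels = bands, ordered = TRUE),
             reduced = reduced)
}

band_levels <- function() {
  c("very poor", "poor", "fair", "good", "excellent", "superior")
}

#' @rdname crf_band
#' @param path optional path to a band-edge CSV (`sex, band, upper`; one
#'   `Inf` upper bound per sex for the top band).
#' @export
crf_band_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "crf_bands_synthetic.csv",
                        package = "kidfitr", mustWork = TRUE)
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sex", "band", "upper")
  if (!all(needed %in% names(tab))) {
    stop_input("band-edge CSV must have columns sex, band, upper")
  }
  tab$upper <- as.numeric(tab$upper)
  bad <- setdiff(unique(tab$band), band_levels())
  if (length(bad)) {
    stop_input(paste("unknown band names:", paste(bad, collapse = ", ")))
  }
  tab
}

#' BMI-for-age category from a percentile
#'
#' Standard growth-chart categories: underweight below the 5th percentile,
#' overweight/obese at or above the 85th, healthy in between.
#'
#' @param bmi_percentile percentile in `[0, 100]` (`NA` passes through).
#' @return Factor with levels `underweight`, `healthy`,
#'   `overweight/obese`.
#' @export
#' @examples
#' bmi_category(c(4.9, 50, 85))
bmi_category <- function(bmi_percentile) {
  ok <- is.na(bmi_percentile) |
    (is.finite(bmi_percentile) & bmi_percentile >= 0 & bmi_percentile <= 100)
  if (!all(ok)) stop_input("`bmi_percentile` must be in [0, 100]")
  out <- ifelse(bmi_percentile >= 85, "overweight/obese",
                ifelse(bmi_percentile < 5, "underweight", "healthy"))
  factor(out, levels = c("underweight", "healthy", "overweight/obese"))
}

#' Motor-proficiency quartile group from a BOT2 percentile rank
#'
#' Quartile group 1 (lowest) covers 0 to the 25th percentile inclusive;
#' each subsequent group has an open lower and closed upper boundary.
#'
#' @param bot2_percentile percentile rank in `[0, 100]` (`NA` passes
#'   through).
#' @return Integer quartile group 1--4.
#' @export
#' @examples
#' motor_quartile(c(25, 25.01, 100))
motor_quartile <- function(bot2_percentile) {
  ok <- is.na(bot2_percentile) |
    (is.finite(bot2_percentile) & bot2_percentile >= 0 & bot2_percentile <= 100)
  if (!all(ok)) stop_input("`bot2_percentile` must be in [0, 100]")
  q <- ifelse(bot2_percentile <= 25, 1L,
              ifelse(bot2_percentile <= 50, 2L,
                     ifelse(bot2_percentile <= 75, 3L, 4L)))
  as.integer(q)
}

#' Classify a whole cohort
#'
#' Appends the screen and all reference-standard classifications to a
#' cohort: predicted VO2max, the two KidFit component flags and overall
#' result, BMI category, motor quartile group, and the CRF band/reduced
#' status of the measured VO2peak (where available).
#'
#' @param cohort a cohort data frame (see [generate_cohort()]).
#' @param rule a [screening_rule()].
#' @param band_table CRF band edges, see [crf_band_table()].
#' @return The cohort with columns `predicted_vo2`, `sams_flag`,
#'   `crf_flag`, `kidfit`, `bmi_category`, `motor_quartile`, `crf_band`,
#'   `crf_reduced` appended.
#' @export
classify_cohort <- function(cohort, rule = screening_rule(),
                            band_table = crf_band_table()) {
  pred <- predict_vo2max(cohort$mstp_score, rule,
                         covariates = cohort)
  res <- classify_kidfit(cohort$sams_time, pred, cohort$sex, rule)
  cohort$predicted_vo2 <- pred
  cohort$sams_flag <- res$sams_flag
  cohort$crf_flag <- res$crf_flag
  cohort$kidfit <- res$overall
  cohort$bmi_category <- if (!is.null(cohort$bmi_percentile)) {
    bmi_category(cohort$bmi_percentile)
  } else NA
  cohort$motor_quartile <- if (!is.null(cohort$bot2_percentile)) {
    motor_quartile(cohort$bot2_percentile)
  } else NA
  if (!is.null(cohort$vo2peak)) {
    cb <- crf_band(cohort$vo2peak, cohort$sex, band_table)
    cohort$crf_band <- cb$band
    cohort$crf_reduced <- cb$reduced
  } else {
    cohort$crf_band <- NA
    cohort$crf_reduced <- NA
  }
  cohort
}
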