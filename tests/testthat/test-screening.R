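test_that("MSTP scoring awards whole and half points", {
  expect_equal(mstp_score(21, TRUE), 21.5)
  expect_equal(mstp_score(0, FALSE), 0)
  expect_equal(mstp_score(22, FALSE), 22.0)
  expect_equal(mstp_score(c(10, 11), c(TRUE, FALSE)), c(10.5, 11))
  expect_error(mstp_score(-1), class = "kidfit_input_error")
  expect_error(mstp_score(3.2), class = "kidfit_input_error")
})

test_that("VO2max prediction evaluates the configured linear equation", {
  rule_const <- screening_rule(vo2_prediction_coefficients = c(intercept = 37))
  expect_equal(predict_vo2max(c(1, 50), rule_const), c(37, 37))

  rule_unit <- screening_rule(vo2_prediction_coefficients = c(intercept = 1, mstp = 1))
  expect_equal(predict_vo2max(10, rule_unit), 11)

  # strictly increasing in MSTP when its coefficient is positive
  rule2 <- screening_rule(vo2_prediction_coefficients = c(intercept = 0, mstp = 2))
  expect_equal(predict_vo2max(21.83, rule2), 43.66)
  pred <- predict_vo2max(seq(0, 30, 0.5), rule2)
  expect_true(all(diff(pred) > 0))

  # default synthetic equation is anchored at the cohort means
  expect_equal(predict_vo2max(21.83, screening_rule()), 43.63, tolerance = 1e-9)

  # covariate coefficients need matching covariates
  rule_age <- screening_rule(
    vo2_prediction_coefficients = c(intercept = 0, mstp = 1, age = -0.5))
  expect_equal(predict_vo2max(20, rule_age, covariates = list(age = 10)), 15)
  expect_error(predict_vo2max(20, rule_age), "covariate",
               class = "kidfit_input_error")

  no_coef <- screening_rule(vo2_prediction_coefficients = NULL)
  expect_error(predict_vo2max(20, no_coef), "prediction coefficients",
               class = "kidfit_config_error")
})

test_that("the positivity rule applies inclusive boundaries on both arms", {
  # SAMS arm only, above the cut-off
  r <- classify_kidfit(6.00, 50.0, "male")
  expect_true(r$sams_flag); expect_false(r$crf_flag)
  expect_equal(as.character(r$overall), "positive")

  # SAMS boundary is inclusive
  r <- classify_kidfit(5.43, 60.0, "female")
  expect_true(r$sams_flag)
  expect_equal(as.character(r$overall), "positive")

  # CRF boundary is inclusive
  r <- classify_kidfit(4.00, 34.9, "female")
  expect_false(r$sams_flag); expect_true(r$crf_flag)
  expect_equal(as.character(r$overall), "positive")

  # negative only when both arms clear
  r <- classify_kidfit(5.42, 35.0, "female")
  expect_equal(as.character(r$overall), "negative")

  # full truth-table grid against a direct transcription of the rule
  grid <- expand.grid(sams = c(4.0, 5.42, 5.43, 6.0),
                      vo2 = c(30, 34.9, 35, 45.1, 45.2, 50),
                      sex = c("female", "male"),
                      stringsAsFactors = FALSE)
  got <- classify_kidfit(grid$sams, grid$vo2, grid$sex)
  cut <- ifelse(grid$sex == "male", 45.1, 34.9)
  expect_equal(got$sams_flag, grid$sams >= 5.43)
  expect_equal(got$crf_flag, grid$vo2 <= cut)
  expect_equal(got$overall == "positive", grid$sams >= 5.43 | grid$vo2 <= cut)

  expect_error(classify_kidfit(5, 40, NA), class = "kidfit_input_error")
  expect_error(classify_kidfit(-1, 40, "male"), class = "kidfit_input_error")
})

test_that("positivity is monotone in SAMS time and predicted VO2", {
  set.seed(42)
  for (i in 1:200) {
    sams <- runif(1, 2, 8)
    vo2 <- runif(1, 20, 60)
    sex <- sample(c("female", "male"), 1)
    base <- classify_kidfit(sams, vo2, sex)$overall == "positive"
    worse <- classify_kidfit(sams + runif(1, 0, 3), vo2 - runif(1, 0, 15),
                             sex)$overall == "positive"
    if (base) expect_true(worse)
  }
})

test_that("BMI categories partition the percentile range with inclusive cut-offs", {
  expect_equal(as.character(bmi_category(85.0)), "overweight/obese")
  expect_equal(as.character(bmi_category(50.0)), "healthy")
  expect_equal(as.character(bmi_category(4.9)), "underweight")
  expect_equal(as.character(bmi_category(5.0)), "healthy")
  # every value gets exactly one category
  p <- seq(0, 100, by = 0.5)
  expect_false(anyNA(bmi_category(p)))
  expect_error(bmi_category(101), class = "kidfit_input_error")

  # a fixture cohort built to the published split: 3 underweight,
  # 16 healthy, 6 overweight/obese out of 25
  pct <- c(runif(3, 0, 4.9), runif(16, 6, 84), runif(6, 85, 99))
  expect_equal(as.integer(table(bmi_category(pct))), c(3, 16, 6))
})

test_that("motor quartile groups follow closed-upper boundaries", {
  expect_equal(motor_quartile(25.0), 1L)
  expect_equal(motor_quartile(25.01), 2L)
  expect_equal(motor_quartile(0), 1L)
  expect_equal(motor_quartile(50), 2L)
  expect_equal(motor_quartile(75), 3L)
  expect_equal(motor_quartile(100.0), 4L)
  p <- seq(0, 100, by = 0.25)
  q <- motor_quartile(p)
  expect_true(all(q %in% 1:4))
  expect_true(all(diff(q) >= 0))
  expect_error(motor_quartile(-0.1), class = "kidfit_input_error")
})

test_that("CRF bands agree with the reduced-CRF screen flag", {
  b <- crf_band(41.32, "female")
  expect_equal(as.character(b$band), "excellent")
  expect_false(b$reduced)

  expect_true(crf_band(34.9, "female")$reduced)
  expect_false(crf_band(35.0, "female")$reduced)
  expect_true(crf_band(45.1, "male")$reduced)
  expect_false(crf_band(45.2, "male")$reduced)

  # reduced flag coincides with the rule's CRF arm on a dense grid
  grid <- expand.grid(vo2 = seq(20, 60, 0.1), sex = c("female", "male"),
                      stringsAsFactors = FALSE)
  reduced <- crf_band(grid$vo2, grid$sex)$reduced
  flag <- classify_kidfit(rep(3, nrow(grid)), grid$vo2, grid$sex)$crf_flag
  expect_equal(reduced, flag)

  expect_error(crf_band(-5, "male"), class = "kidfit_input_error")
})

test_that("LMS z-scores match their defining transformation", {
  # the median maps to z = 0, percentile 50
  expect_equal(lms_zscore(20, l = -1.5, m = 20, s = 0.1), 0)
  expect_equal(lms_percentile(20, l = 2, m = 20, s = 0.1), 50)

  # L = 1 reduces to (x/M - 1)/S
  expect_equal(lms_zscore(22, l = 1, m = 20, s = 0.1), 1)

  # continuity in L around 0.5 (numeric-limit oracle)
  z_mid <- lms_zscore(22, l = 0.5, m = 20, s = 0.1)
  z_lo <- lms_zscore(22, l = 0.5 - 1e-6, m = 20, s = 0.1)
  z_hi <- lms_zscore(22, l = 0.5 + 1e-6, m = 20, s = 0.1)
  expect_lt(abs(z_mid - z_lo), 1e-4)
  expect_lt(abs(z_mid - z_hi), 1e-4)

  # L = 0 log branch is the limit of the power branch
  expect_lt(abs(lms_zscore(22, l = 0, m = 20, s = 0.1) -
                  lms_zscore(22, l = 1e-8, m = 20, s = 0.1)), 1e-6)

  # strictly increasing in x; percentiles stay inside (0, 100)
  x <- seq(10, 40, 0.5)
  z <- lms_zscore(x, l = -2, m = 18, s = 0.12)
  expect_true(all(diff(z) > 0))
  pc <- lms_percentile(x, l = -2, m = 18, s = 0.12)
  expect_true(all(pc > 0 & pc < 100))

  expect_error(lms_zscore(-1, 1, 20, 0.1), class = "kidfit_input_error")
})

test_that("LMS lookup interpolates linearly in age within each sex", {
  tab <- read_lms_table()
  rows <- tab[tab$sex == "female", ]
  a1 <- rows$agemos[1]; a2 <- rows$agemos[2]
  mid <- lms_lookup(tab, "female", (a1 + a2) / 2)
  expect_equal(mid$M, (rows$M[1] + rows$M[2]) / 2)
  expect_equal(mid$L, (rows$L[1] + rows$L[2]) / 2)
  # ages beyond the table clamp to the boundary row
  low <- lms_lookup(tab, "female", a1 - 100)
  expect_equal(low$M, rows$M[1])
  expect_error(lms_lookup(tab, "unknown", 120), class = "kidfit_input_error")

  pct <- bmi_percentile_lms(18, "female", 132)
  expect_true(pct > 0 && pct < 100)
})

test_that("classify_cohort appends consistent per-child classifications", {
  co <- generate_cohort(cohort_config(n = 200, seed = 21))
  cl <- classify_cohort(co)
  expect_equal(cl$kidfit == "positive", cl$sams_flag | cl$crf_flag)
  expect_equal(is.na(cl$crf_reduced), is.na(co$vo2peak))
  expect_equal(cl$motor_quartile, motor_quartile(co$bot2_percentile))
  meas <- !is.na(co$vo2peak)
  expect_equal(cl$crf_reduced[meas],
               classify_kidfit(rep(3, sum(meas)), co$vo2peak[meas],
                               co$sex[meas])$crf_flag)
})
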