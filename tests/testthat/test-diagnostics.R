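test_that("confusion tables tally screens against states correctly", {
  t <- build_confusion(c("positive", "positive", "negative"),
                       c("diseased", "healthy", "healthy"))
  expect_equal(unlist(t[c("tp", "fn", "fp", "tn")]),
               c(tp = 1, fn = 0, fp = 1, tn = 1))

  # a perfect screen has no off-diagonal mass
  state <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  t <- build_confusion(state, state)
  expect_equal(t$fp + t$fn, 0)
  expect_equal(t$tp + t$tn, 50)

  # brute-force tally oracle on random vectors
  set.seed(11)
  screen <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  state <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  t <- build_confusion(screen, state)
  manual <- c(tp = 0, fn = 0, fp = 0, tn = 0)
  for (i in 1:200) {
    key <- if (screen[i] && state[i]) "tp" else if (!screen[i] && state[i]) "fn"
      else if (screen[i]) "fp" else "tn"
    manual[key] <- manual[key] + 1
  }
  expect_equal(unlist(t[c("tp", "fn", "fp", "tn")]), manual)

  expect_error(build_confusion(c(TRUE, FALSE), TRUE),
               class = "kidfit_input_error")
  expect_error(build_confusion(logical(0), logical(0)),
               class = "kidfit_input_error")
  expect_error(confusion_table(1, -1, 0, 0), class = "kidfit_input_error")
})

test_that("proportion estimates and Wald SEs reproduce frozen values", {
  pr <- screen_proportions(confusion_table(9, 1, 12, 35))
  expect_equal(pr$estimate, c(0.90, 35 / 47, 9 / 21, 35 / 36), tolerance = 1e-12)
  expect_equal(pr$se,
               c(sqrt(0.9 * 0.1 / 10), sqrt((35 / 47) * (12 / 47) / 47),
                 sqrt((9 / 21) * (12 / 21) / 21), sqrt((35 / 36) * (1 / 36) / 36)),
               tolerance = 1e-12)

  pr <- screen_proportions(confusion_table(6, 0, 4, 15))
  expect_equal(pr$estimate[pr$statistic == "sensitivity"], 1)
  expect_equal(pr$se[pr$statistic == "sensitivity"], 0)
  expect_equal(pr$estimate[pr$statistic == "npv"], 1)
  expect_equal(pr$se[pr$statistic == "npv"], 0)

  pr <- screen_proportions(confusion_table(1, 1, 1, 1))
  expect_equal(pr$estimate, rep(0.5, 4))
  expect_equal(pr$se, rep(sqrt(0.25 / 2), 4))

  # zero denominator -> that estimate undefined, others intact
  pr <- screen_proportions(confusion_table(0, 0, 4, 16))
  expect_true(is.na(pr$estimate[pr$statistic == "sensitivity"]))
  expect_equal(pr$estimate[pr$statistic == "specificity"], 0.8)
})

test_that("likelihood ratios carry Simel log-method intervals", {
  lr <- likelihood_ratios(confusion_table(9, 1, 12, 35))
  expect_equal(lr$estimate[1], 0.9 / (12 / 47), tolerance = 1e-12)
  expect_equal(lr$lower[1], 2.0745, tolerance = 1e-4)
  expect_equal(lr$upper[1], 5.9897, tolerance = 1e-4)
  expect_equal(lr$estimate[2], 0.1 / (35 / 47), tolerance = 1e-12)
  expect_equal(lr$lower[2], 0.02077, tolerance = 1e-3)
  expect_equal(lr$upper[2], 0.86862, tolerance = 1e-4)

  # FN = 0: LR- collapses to 0 with an undefined interval
  lr <- likelihood_ratios(confusion_table(6, 0, 4, 15))
  expect_equal(lr$estimate[2], 0)
  expect_true(is.na(lr$lower[2]) && is.na(lr$upper[2]))
  expect_equal(lr$estimate[1], 4.75, tolerance = 1e-12)

  # FP = 0 (specificity 1): LR+ undefined
  lr <- likelihood_ratios(confusion_table(5, 5, 0, 10))
  expect_true(is.na(lr$estimate[1]))

  # LR+ > 1 > LR- whenever sens + spec > 1
  set.seed(22)
  for (i in 1:50) {
    t <- random_confusion()
    pr <- screen_proportions(t)
    sens <- pr$estimate[1]; spec <- pr$estimate[2]
    if (anyNA(c(sens, spec)) || sens + spec <= 1 || spec %in% c(0, 1)) next
    lr <- likelihood_ratios(t)
    expect_gt(lr$estimate[1], 1)
    expect_lt(lr$estimate[2], 1)
  }
})

test_that("odds ratios use Haldane correction only when a cell is zero", {
  or <- odds_ratio(confusion_table(6, 0, 4, 15))
  expect_true(or$corrected)
  expect_equal(or$estimate, (6.5 * 15.5) / (0.5 * 4.5), tolerance = 1e-12)
  expect_equal(round(or$estimate, 2), 44.78)

  or <- odds_ratio(confusion_table(9, 1, 12, 35))
  expect_false(or$corrected)
  expect_equal(or$estimate, 26.25, tolerance = 1e-12)
  expect_equal(or$lower, 3.0046, tolerance = 1e-4)
  expect_equal(or$upper, 229.3367, tolerance = 1e-4)

  or <- odds_ratio(confusion_table(1, 1, 1, 1))
  expect_equal(or$estimate, 1)
  expect_true(or$lower < 1 && or$upper > 1)

  # label-swap duality on uncorrected tables: OR -> 1/OR
  set.seed(33)
  for (i in 1:30) {
    t <- random_confusion()
    if (any(unlist(t[c("tp", "fn", "fp", "tn")]) == 0)) next
    swapped <- confusion_table(t$fn, t$tp, t$tn, t$fp)
    expect_equal(odds_ratio(swapped)$estimate, 1 / odds_ratio(t)$estimate,
                 tolerance = 1e-12)
  }
})

test_that("efficiency rate is the correct-classification proportion", {
  expect_equal(efficiency_rate(confusion_table(6, 0, 4, 15)), 0.84)
  expect_equal(efficiency_rate(confusion_table(7, 0, 3, 14)), 0.875)
  expect_equal(efficiency_rate(confusion_table(0, 5, 5, 0)), 0)

  # exact identity ER = sens * prev + spec * (1 - prev)
  set.seed(44)
  for (i in 1:50) {
    t <- random_confusion()
    n1 <- t$tp + t$fn; n0 <- t$fp + t$tn
    if (n1 == 0 || n0 == 0) next
    prev <- n1 / (n1 + n0)
    expect_equal(efficiency_rate(t),
                 (t$tp / n1) * prev + (t$tn / n0) * (1 - prev),
                 tolerance = 1e-12)
  }
})

test_that("the exact test matches enumeration and the stats reference", {
  # empty margin carries no information
  expect_equal(fisher_exact(confusion_table(0, 0, 5, 5)), 1)
  expect_equal(fisher_exact(confusion_table(3, 4, 0, 0)), 1)

  set.seed(55)
  for (i in 1:100) {
    t <- random_confusion(60)
    p <- fisher_exact(t)
    expect_equal(p, oracle_fisher(t$tp, t$fn, t$fp, t$tn), tolerance = 1e-10)
    m <- matrix(c(t$tp, t$fn, t$fp, t$tn), 2)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      expect_equal(p, fisher.test(m)$p.value, tolerance = 1e-9)
    }
    # invariant under transposing the table
    transposed <- confusion_table(t$tp, t$fp, t$fn, t$tn)
    expect_equal(fisher_exact(transposed), p, tolerance = 1e-12)
  }
})

test_that("diagnostic_summary bundles all statistics coherently", {
  ds <- diagnostic_summary(confusion_table(9, 1, 12, 35))
  expect_s3_class(ds, "diagnostic_summary")
  expect_equal(ds$efficiency_rate, 44 / 57)
  expect_true(ds$odds_ratio$lower <= ds$odds_ratio$estimate)
  expect_true(ds$odds_ratio$estimate <= ds$odds_ratio$upper)
  lr <- ds$likelihood_ratios
  expect_true(all(lr$lower <= lr$estimate & lr$estimate <= lr$upper,
                  na.rm = TRUE))
  # construction from raw vectors matches construction from counts
  screen <- rep(c(TRUE, FALSE, TRUE, FALSE), c(9 + 12, 1 + 35, 0, 0))
  state <- c(rep(TRUE, 9), rep(FALSE, 12), rep(TRUE, 1), rep(FALSE, 35))
  ds2 <- diagnostic_summary(screen = screen, state = state)
  expect_equal(ds2$proportions, ds$proportions)
  expect_output(print(ds), "efficiency_rate")
})
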