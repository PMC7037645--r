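#' Sensitivity, specificity and predictive values with Wald SEs
#'
#' Point estimates are the usual cell ratios; each standard error is the
#' binomial Wald form `sqrt(p (1 - p) / m)` with `m` the estimate's own
#' denominator. An estimate with a zero denominator is returned as `NA`
#' (undefined) rather than raising an error for the whole table.
#'
#' @param t a [confusion_table()].
#' @return A data frame with columns `statistic`, `estimate`, `se` and
#'   rows `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
#' @examples
#' screen_proportions(confusion_table(9, 1, 12, 35))
screen_proportions <- function(t) {
  prop <- function(num, den) {
    if (den == 0) return(c(NA_real_, NA_real_))
    p <- num / den
    c(p, sqrt(p * (1 - p) / den))
  }
  vals <- rbind(
    sensitivity = prop(t$tp, t$tp + t$fn),
    specificity = prop(t$tn, t$tn + t$fp),
    ppv = prop(t$tp, t$tp + t$fp),
    npv = prop(t$tn, t$tn + t$fn)
  )
  data.frame(statistic = rownames(vals), estimate = vals[, 1], se = vals[, 2],
             row.names = NULL)
}

#' Likelihood ratios with log-method confidence intervals
#'
#' `LR+ = sens / (1 - spec)` and `LR- = (1 - sens) / spec`, with
#' confidence intervals obtained by exponentiating `log(LR) +/- z * SE`
#' where `SE(log LR+) = sqrt(1/TP - 1/(TP+FN) + 1/FP - 1/(FP+TN))` and
#' the analogous form with FN, TN for LR-. When a numerator cell is zero
#' the ratio is reported as 0 with an undefined (`NA`) interval; when
#' specificity is 1 (no false positives) LR+ is undefined.
#'
#' @param t a [confusion_table()].
#' @param conf_level confidence level (default 0.95).
#' @return A data frame with rows `lr_pos`, `lr_neg` and columns
#'   `estimate`, `lower`, `upper`.
#' @export
#' @examples
#' likelihood_ratios(confusion_table(9, 1, 12, 35))
likelihood_ratios <- function(t, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  n1 <- t$tp + t$fn
  n0 <- t$fp + t$tn
  sens <- if (n1 > 0) t$tp / n1 else NA_real_
  spec <- if (n0 > 0) t$tn / n0 else NA_real_

  lr_ci <- function(est, a, c1, b, c0) {
    # log-method interval; requires all four contributing cells positive
    if (a == 0 || b == 0) return(c(NA_real_, NA_real_))
    se <- sqrt(1 / a - 1 / c1 + 1 / b - 1 / c0)
    exp(log(est) + c(-1, 1) * z * se)
  }

  if (is.na(spec) || spec == 1) {
    lr_pos <- c(NA_real_, NA_real_, NA_real_)
  } else {
    est <- sens / (1 - spec)
    lr_pos <- c(est, lr_ci(est, t$tp, n1, t$fp, n0))
  }
  if (is.na(spec) || spec == 0) {
    lr_neg <- c(NA_real_, NA_real_, NA_real_)
  } else {
    est <- (1 - sens) / spec
    lr_neg <- c(est, lr_ci(est, t$fn, n1, t$tn, n0))
  }
  data.frame(statistic = c("lr_pos", "lr_neg"),
             estimate = c(lr_pos[1], lr_neg[1]),
             lower = c(lr_pos[2], lr_neg[2]),
             upper = c(lr_pos[3], lr_neg[3]),
             row.names = NULL)
}

#' Odds ratio with Woolf interval and Haldane-Anscombe correction
#'
#' `OR = (TP * TN) / (FN * FP)`. If any cell is zero, 0.5 is added to all
#' four cells (Haldane-Anscombe) before computing the estimate and its
#' Woolf (log) confidence interval
#' `exp(log OR +/- z * sqrt(1/TP' + 1/FN' + 1/FP' + 1/TN'))`; the
#' `corrected` flag records that the correction was applied.
#'
#' @inheritParams likelihood_ratios
#' @return A list with `estimate`, `lower`, `upper`, `corrected`.
#' @export
#' @examples
#' odds_ratio(confusion_table(6, 0, 4, 15)) # corrected, 44.78
odds_ratio <- function(t, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  cells <- c(t$tp, t$fn, t$fp, t$tn)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  est <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(est) + c(-1, 1) * z * se)
  list(estimate = est, lower = ci[1], upper = ci[2], corrected = corrected)
}

#' Efficiency rate (correct classification rate)
#'
#' The proportion of all children correctly classified,
#' `(TP + TN) / N`. Identically equal to
#' `sens * prevalence + spec * (1 - prevalence)`.
#'
#' @param t a [confusion_table()].
#' @return A proportion in `[0, 1]`.
#' @export
#' @examples
#' efficiency_rate(confusion_table(6, 0, 4, 15)) # 0.84
efficiency_rate <- function(t) {
  (t$tp + t$tn) / n_total(t)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under the point-probability ("minlike")
#' definition: with both margins fixed, the p-value is the sum of
#' hypergeometric probabilities of all tables whose point probability
#' does not exceed that of the observed table (a relative tolerance of
#' 1e-7 guards floating-point ties). A table with an empty margin carries
#' no information and returns p = 1.
#'
#' @param t a [confusion_table()].
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact(confusion_table(6, 0, 4, 15))
fisher_exact <- function(t) {
  n <- n_total(t)
  r1 <- t$tp + t$fp   # screen-positive margin
  c1 <- t$tp + t$fn   # diseased margin
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(t$tp, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Full diagnostic-accuracy summary for one screen/reference pair
#'
#' Bundles every 2x2 statistic used to validate the KidFit screen:
#' sensitivity, specificity, PPV and NPV with Wald SEs; positive and
#' negative likelihood ratios with log-method CIs; the odds ratio with
#' Woolf CI (Haldane-Anscombe corrected when a cell is zero); the
#' efficiency rate; and the two-sided Fisher exact p-value.
#'
#' @param t a [confusion_table()], or `NULL` if supplying `screen`/`state`.
#' @param screen,state optional per-child vectors forwarded to
#'   [build_confusion()] when `t` is not given.
#' @param conf_level confidence level for the ratio intervals.
#' @return An object of class `diagnostic_summary`.
#' @export
#' @examples
#' diagnostic_summary(confusion_table(9, 1, 12, 35))
diagnostic_summary <- function(t = NULL, screen = NULL, state = NULL,
                               conf_level = 0.95) {
  if (is.null(t)) t <- build_confusion(screen, state)
  if (!inherits(t, "confusion_table")) t <- do.call(confusion_table, as.list(t))
  structure(
    list(
      table = t,
      proportions = screen_proportions(t),
      likelihood_ratios = likelihood_ratios(t, conf_level),
      odds_ratio = odds_ratio(t, conf_level),
      efficiency_rate = efficiency_rate(t),
      fisher_p = fisher_exact(t),
      conf_level = conf_level
    ),
    class = "diagnostic_summary"
  )
}

# single formatting layer: printed report values at the conventional
# rounding (percentages and their SEs; ratios and rates to 2 dp)
format_diagnostic_summary <- function(x) {
  pr <- x$proportions
  get <- function(stat, col) pr[pr$statistic == stat, col]
  lr <- x$likelihood_ratios
  lr_fmt <- function(row) {
    if (is.na(lr$estimate[row])) return("-")
    if (is.na(lr$lower[row])) return(sprintf("%.2f (-)", lr$estimate[row]))
    sprintf("%.2f (%.2f-%.2f)", lr$estimate[row], lr$lower[row], lr$upper[row])
  }
  or <- x$odds_ratio
  c(
    cells = sprintf("TP=%d FN=%d FP=%d TN=%d", x$table$tp, x$table$fn,
                    x$table$fp, x$table$tn),
    sensitivity = sprintf("%.2f%% (%.3f)", 100 * get("sensitivity", "estimate"),
                          get("sensitivity", "se")),
    specificity = sprintf("%.2f%% (%.3f)", 100 * get("specificity", "estimate"),
                          get("specificity", "se")),
    ppv = sprintf("%.0f%% (%.3f)", 100 * get("ppv", "estimate"),
                  get("ppv", "se")),
    npv = sprintf("%.0f%% (%.3f)", 100 * get("npv", "estimate"),
                  get("npv", "se")),
    lr_pos = lr_fmt(1),
    lr_neg = lr_fmt(2),
    odds_ratio = sprintf("%.2f (%.2f-%.2f)%s", or$estimate, or$lower,
                         or$upper, if (or$corrected) " [corrected]" else ""),
    efficiency_rate = sprintf("%.2f", x$efficiency_rate),
    fisher_p = if (x$fisher_p < 0.001) "<0.001" else sprintf("%.3f", x$fisher_p)
  )
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat("<diagnostic_summary>\n")
  vals <- format_diagnostic_summary(x)
  for (nm in names(vals)) cat(sprintf("  %-16s %s\n", nm, vals[[nm]]))
  invisible(x)
}
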