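#' Multiple linear regression with standardized betas
#'
#' Simultaneous-entry least-squares fit of an outcome on a set of
#' predictors, reported the way concurrent-validity models are usually
#' tabulated: the model R-squared with its overall-F p-value, and per
#' predictor the standardized beta (`b_j * sd(x_j) / sd(y)`) with its
#' t-test p-value. Rows with any missing value are dropped (listwise
#' deletion), so the per-model `n` follows available cases.
#'
#' @param outcome numeric outcome vector.
#' @param predictors named list or data frame of numeric predictors.
#' @return An object of class `kidfit_regression`: list with `r_squared`,
#'   `model_p`, `betas` (data frame: `predictor`, `beta`, `b`, `t`, `p`),
#'   `n`, `fit` (the underlying `lm`).
#' @export
#' @examples
#' x <- rnorm(30); y <- 2 * x + rnorm(30)
#' fit_ols(y, list(x = x))$r_squared
fit_ols <- function(outcome, predictors) {
  X <- as.data.frame(predictors)
  if (ncol(X) == 0) stop_input("at least one predictor is required")
  dat <- cbind(data.frame(.y = outcome), X)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n <= ncol(X) + 1) {
    stop_input("not enough complete cases for the number of predictors")
  }
  fit <- lm(.y ~ ., data = dat)
  if (anyNA(coef(fit))) {
    dropped <- names(coef(fit))[is.na(coef(fit))]
    stop_input(paste("rank-deficient design; collinear predictors:",
                     paste(dropped, collapse = ", ")))
  }
  sm <- summary(fit)
  r2 <- sm$r.squared
  fstat <- sm$fstatistic
  model_p <- pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  b <- coef(fit)[-1]
  sds <- vapply(dat[names(X)], sd, numeric(1))
  betas <- data.frame(
    predictor = names(X),
    beta = unname(b * sds / sd(dat$.y)),
    b = unname(b),
    t = unname(sm$coefficients[-1, "t value"]),
    p = unname(sm$coefficients[-1, "Pr(>|t|)"]),
    row.names = NULL
  )
  structure(
    list(r_squared = r2, model_p = unname(model_p), betas = betas,
         n = n, fit = fit),
    class = "kidfit_regression"
  )
}

#' @export
print.kidfit_regression <- function(x, ...) {
  cat(sprintf("<kidfit_regression> n = %d, R^2 = %.3f (p %s)\n",
              x$n, x$r_squared, format.pval(x$model_p, digits = 3)))
  b <- x$betas
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %-12s beta = %+.3f (p %s)\n", b$predictor[i], b$beta[i],
                format.pval(b$p[i], digits = 3)))
  }
  invisible(x)
}

#' Independent-samples pooled-variance t-test
#'
#' Classic two-sample t-test with pooled variance and
#' `df = n1 + n2 - 2`, the form whose degrees of freedom match a
#' 57-child cohort reporting DF = 55. Returns an undefined marker
#' (`NA` statistic, p) when the pooled variance is zero.
#'
#' @param group_a,group_b numeric vectors (each of length >= 2; `NA`s
#'   dropped).
#' @return A list with `t`, `df`, `p`, `mean_difference`
#'   (mean of `group_a` minus mean of `group_b`).
#' @export
#' @examples
#' ttest_independent(rnorm(20), rnorm(20, 1))
ttest_independent <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop_input("each group needs at least two non-missing observations")
  }
  df <- length(a) + length(b) - 2L
  md <- mean(a) - mean(b)
  pooled_var <- ((length(a) - 1) * stats::var(a) +
                   (length(b) - 1) * stats::var(b)) / df
  if (pooled_var == 0) {
    return(list(t = NA_real_, df = df, p = NA_real_, mean_difference = md))
  }
  ht <- t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_difference = md)
}
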