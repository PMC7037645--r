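#' Empirical ROC curve with AUC, Hanley-McNeil SE and accuracy band
#'
#' Sweeps every distinct score threshold to trace the empirical ROC and
#' integrates it by the trapezoidal rule. With ties counted one half, the
#' resulting AUC equals the Mann-Whitney probability that a randomly
#' chosen diseased child scores higher than a healthy one. The standard
#' error uses the Hanley-McNeil formula, the 95% interval is
#' `AUC +/- z * SE` clipped to `[0, 1]`, the p-value tests AUC = 0.5, and
#' the accuracy band follows the conventional screening criteria (see
#' [auc_band()]).
#'
#' @param scores continuous marker values, one per child.
#' @param state reference states, `"diseased"`/`"healthy"` or logical
#'   (TRUE = diseased).
#' @param direction `"higher_is_diseased"` (default) or
#'   `"lower_is_diseased"`; the score is negated in the latter case so
#'   larger transformed scores always indicate disease.
#' @param conf_level confidence level for the AUC interval.
#' @return An object of class `kidfit_roc`: list with `points` (a data
#'   frame of `threshold`, `fpr`, `sensitivity` from (0,0) to (1,1)),
#'   `auc`, `auc_se`, `ci`, `p_value`, `band`, `n_diseased`, `n_healthy`.
#' @export
#' @examples
#' roc <- roc_curve(c(1, 2, 3, 4, 5, 6), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
#' roc$auc # 1: complete separation
roc_curve <- function(scores, state,
                      direction = c("higher_is_diseased", "lower_is_diseased"),
                      conf_level = 0.95) {
  direction <- match.arg(direction)
  if (length(scores) != length(state)) {
    stop_input("`scores` and `state` must have the same length")
  }
  dis <- as_binary(state, "diseased", "healthy", "state")
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop_input("`scores` must be finite with no missing values")
  }
  n1 <- sum(dis)
  n0 <- sum(!dis)
  if (n1 == 0 || n0 == 0) {
    stop_input("need at least one diseased and one healthy record")
  }
  s <- if (direction == "lower_is_diseased") -scores else scores

  thresholds <- sort(unique(s), decreasing = TRUE)
  sens <- vapply(thresholds, function(th) mean(s[dis] >= th), numeric(1))
  fpr <- vapply(thresholds, function(th) mean(s[!dis] >= th), numeric(1))
  points <- data.frame(
    threshold = c(Inf, thresholds),
    fpr = c(0, fpr),
    sensitivity = c(0, sens)
  )
  if (points$fpr[nrow(points)] != 1 || points$sensitivity[nrow(points)] != 1) {
    points <- rbind(points, data.frame(threshold = -Inf, fpr = 1, sensitivity = 1))
  }
  auc <- sum(diff(points$fpr) *
               (utils::head(points$sensitivity, -1) +
                  utils::tail(points$sensitivity, -1)) / 2)

  # Hanley-McNeil variance
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- clamp(auc + c(-1, 1) * z * se, 0, 1)
  p <- if (se == 0) {
    if (auc == 0.5) 1 else 0
  } else {
    2 * pnorm(-abs(auc - 0.5) / se)
  }
  structure(
    list(points = points, auc = auc, auc_se = se, ci = ci, p_value = p,
         band = auc_band(auc), n_diseased = n1, n_healthy = n0,
         direction = direction, conf_level = conf_level),
    class = "kidfit_roc"
  )
}

#' Accuracy band for an AUC value
#'
#' Conventional screening-evidence bands: below 0.5 random; 0.5 up to
#' (but excluding) 0.7 poor; 0.7 up to (but excluding) 0.9 moderate; 0.9
#' and above high. The shared 0.9 boundary is resolved upward to "high".
#'
#' @param auc AUC value(s) in `[0, 1]`.
#' @return Factor with levels `random`, `poor`, `moderate`, `high`.
#' @export
#' @examples
#' auc_band(c(0.895, 0.912))
auc_band <- function(auc) {
  if (any(!is.finite(auc)) || any(auc < 0) || any(auc > 1)) {
    stop_input("`auc` must be in [0, 1]")
  }
  out <- ifelse(auc < 0.5, "random",
                ifelse(auc < 0.7, "poor",
                       ifelse(auc < 0.9, "moderate", "high")))
  factor(out, levels = c("random", "poor", "moderate", "high"))
}

#' @export
print.kidfit_roc <- function(x, ...) {
  cat("<kidfit_roc>\n")
  cat(sprintf("  AUC %.3f (SE %.3f), %d%% CI %.3f-%.3f, p %s, band: %s\n",
              x$auc, x$auc_se, round(100 * x$conf_level), x$ci[1], x$ci[2],
              format.pval(x$p_value, digits = 3), as.character(x$band)))
  cat(sprintf("  %d diseased vs %d healthy, %d ROC points\n",
              x$n_diseased, x$n_healthy, nrow(x$points)))
  invisible(x)
}
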