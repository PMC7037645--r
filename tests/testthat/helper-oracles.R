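# Independent oracles used across the suite. Each is deliberately a
# different computation path from the package implementation.

# two-sided exact p by brute-force enumeration over all tables with the
# observed margins, point probabilities from log-binomial coefficients
oracle_fisher <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  r1 <- tp + fp
  c1 <- tp + fn
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, ks) + lchoose(n - c1, r1 - ks) - lchoose(n, r1)
  probs <- exp(logp)
  p_obs <- exp(lchoose(c1, tp) + lchoose(n - c1, r1 - tp) - lchoose(n, r1))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC as the exhaustive pairwise Mann-Whitney count (ties worth 0.5)
oracle_auc <- function(scores, diseased) {
  sd_ <- scores[diseased]
  sh <- scores[!diseased]
  total <- 0
  for (x in sd_) for (y in sh) {
    total <- total + (x > y) + 0.5 * (x == y)
  }
  total / (length(sd_) * length(sh))
}

# OLS coefficients straight from the normal equations
oracle_ols_coef <- function(y, X) {
  Xm <- cbind(1, as.matrix(X))
  solve(t(Xm) %*% Xm, t(Xm) %*% y)[, 1]
}

# pooled-variance two-sample t from the textbook formula
oracle_ttest <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = n1 + n2 - 2,
       p = 2 * pt(-abs(tval), n1 + n2 - 2))
}

random_confusion <- function(max_n = 60) {
  cells <- as.integer(rmultinom(1, sample(4:max_n, 1), rep(0.25, 4)))
  confusion_table(cells[1], cells[2], cells[3], cells[4])
}

n_total <- function(t) t$tp + t$fn + t$fp + t$tn
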