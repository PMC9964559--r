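# Independent oracles used throughout the suite. These deliberately do
# not share code with the implementation paths they check.

# Random feasible LP instance shaped like a small flux polytope:
# v = 0 is always feasible (lb <= 0 <= ub), bounds finite.
random_lp_network <- function(seed, n_max = 12L, m_max = 7L) {
  set.seed(seed)
  n <- sample(6:n_max, 1)
  m <- sample(3:m_max, 1)
  S <- matrix(0, m, n)
  for (j in seq_len(n)) {
    rows <- sample(m, sample(1:2, 1))
    S[rows, j] <- sample(c(-2, -1, 1, 2), length(rows), replace = TRUE)
  }
  ub <- round(runif(n, 0.5, 10), 2)
  lb <- ifelse(runif(n) < 0.5, 0, -round(runif(n, 0.5, 10), 2))
  w <- round(runif(n, -1, 2), 2)
  list(S = S, lb = lb, ub = ub, w = w)
}

# Exhaustive permutation null for the two-group log-rank statistic:
# all assignments of the observed group sizes, exact p as the fraction
# of assignments with a statistic at least as large.
perm_logrank_p <- function(labels, surv) {
  ids <- surv$sample_id
  labels <- labels[ids]
  k <- sum(labels == labels[1])
  obs <- logrank(labels, surv)$statistic
  combos <- combn(length(ids), k)
  stats <- apply(combos, 2, function(idx) {
    lab <- rep("b", length(ids))
    lab[idx] <- "a"
    logrank(stats::setNames(lab, ids), surv)$statistic
  })
  mean(stats >= obs - 1e-9)
}

# Hand-rolled ordinary two-sample t on each row (equal-variance pooled).
plain_t <- function(y, i1, i0) {
  n1 <- length(i1); n0 <- length(i0)
  m1 <- rowMeans(y[, i1, drop = FALSE]); m0 <- rowMeans(y[, i0, drop = FALSE])
  sp2 <- (rowSums((y[, i1, drop = FALSE] - m1)^2) +
            rowSums((y[, i0, drop = FALSE] - m0)^2)) / (n1 + n0 - 2)
  (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

# Simulated two-group exponential cohort with a given true hazard ratio.
sim_two_group <- function(n, hr, seed, l0 = 0.05, cmax = 75) {
  set.seed(seed)
  g <- rep(c("high", "low"), length.out = n)
  rate <- ifelse(g == "high", l0 * hr, l0)
  Tt <- rexp(n, rate); U <- runif(n, 0, cmax)
  ids <- sprintf("S%d", seq_len(n))
  list(labels = stats::setNames(g, ids),
       surv = survival_records(ids, pmax(pmin(Tt, U), 1e-6), as.integer(Tt <= U)))
}
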