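# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# AUC by exhaustive pair counting: wins + half-ties over all (case, control)
# pairs.
brute_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# C(N, n) draws of the gene list from the universe
enum_hyper_tail <- function(N, K, n, k) {
  marked <- seq_len(K)
  draws <- combn(N, n)
  mean(colSums(matrix(draws %in% marked, nrow = n)) >= k)
}

# Benjamini-Hochberg by the step-up definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Kaplan-Meier product-limit estimator computed directly
product_limit <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  surv <- numeric(length(tt)); s <- 1
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = tt, surv = surv)
}

# least-squares residuals of y on (1, x) via the normal equations
normal_eq_resid <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

# small preprocessed synthetic cohort used by several tests
small_cohort <- function(seed = 42, n = 80, nGenes = 120, ...) {
  preprocessCohort(simulateCohort(cohortSpec(nSamples = n, nGenes = nGenes,
                                             seed = seed, ...)))
}
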