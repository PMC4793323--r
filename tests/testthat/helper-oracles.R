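# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: point probabilities via lgamma (not dhyper-based
# shortcuts through the same helper), likelihoods via naive per-row sums,
# integrals via dense trapezoid rules.

# two-sided Fisher p by direct enumeration over the hypergeometric support,
# point probabilities from log-factorials
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  lp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(lp)
  p_obs <- probs[support == a]
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

# naive per-row Bernoulli log-likelihood
oracle_loglik_fixed <- function(beta, X, y) {
  total <- 0
  for (i in seq_len(nrow(X))) {
    p <- 1 / (1 + exp(-sum(X[i, ] * beta)))
    total <- total + ifelse(y[i] == 1, log(p), log(1 - p))
  }
  total
}

# dense trapezoid integration of the per-cluster marginal likelihood over
# u in [-8 sigma, 8 sigma]
oracle_loglik_marginal <- function(beta, sigma, design, n_grid = 1e5) {
  X <- cbind(1, as.matrix(design[setdiff(names(design), c("y", "cluster"))]))
  y <- design$y
  eta0 <- drop(X %*% beta)
  us <- seq(-8 * sigma, 8 * sigma, length.out = n_grid)
  log_phi <- dnorm(us, 0, sigma, log = TRUE)
  total <- 0
  for (cl in unique(design$cluster)) {
    idx <- design$cluster == cl
    lp <- vapply(us, function(u) {
      eta <- eta0[idx] + u
      sum(y[idx] * eta - log(1 + exp(eta)))
    }, numeric(1))
    v <- lp + log_phi
    m <- max(v)
    total <- total + m + log(sum(exp(v - m)) * (us[2] - us[1]))
  }
  total
}

# small clustered logistic design for GLMM tests
tiny_design <- function(seed = 1, n_clusters = 3, per_cluster = 5) {
  set.seed(seed)
  n <- n_clusters * per_cluster
  cl <- rep(seq_len(n_clusters), each = per_cluster)
  x <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + x))
  tibble::tibble(y = y, x = x, cluster = cl)
}
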