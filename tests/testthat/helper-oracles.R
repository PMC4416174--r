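# Independent brute-force oracles used to validate the dynamic-programming
# implementations. All enumerate the 2^N state paths directly and never call
# the package's recursions.

# joint log-probability of one complete path under the binomial-emission HMM
path_log_prob <- function(z, x, t, pi, A, p) {
  lp <- log(if (z[1] == 1) pi else 1 - pi) + dbinom(x[1], t[1], p[z[1]], log = TRUE)
  for (n in seq_along(z)[-1]) {
    lp <- lp + log(A[z[n - 1], z[n]]) + dbinom(x[n], t[n], p[z[n]], log = TRUE)
  }
  lp
}

all_paths <- function(N) {
  as.matrix(expand.grid(rep(list(1:2), N)))
}

# exact posteriors by exhaustive enumeration
enum_posteriors <- function(x, t, pi, A, p) {
  N <- length(x)
  paths <- all_paths(N)
  lp <- apply(paths, 1, path_log_prob, x = x, t = t, pi = pi, A = A, p = p)
  m <- max(lp)
  w <- exp(lp - m)
  loglik <- m + log(sum(w))
  post <- w / sum(w)
  gamma <- sapply(1:2, function(k) {
    vapply(seq_len(N), function(n) sum(post[paths[, n] == k]), numeric(1))
  })
  gamma <- matrix(gamma, N, 2)
  eps <- array(0, dim = c(max(N - 1, 0), 2, 2))
  if (N > 1) {
    for (n in 2:N) for (j in 1:2) for (k in 1:2) {
      eps[n - 1, j, k] <- sum(post[paths[, n - 1] == j & paths[, n] == k])
    }
  }
  list(gamma = gamma, epsilon = eps, log_likelihood = loglik)
}

# MAP path by enumeration; returns all maximizing paths (for tie awareness)
enum_viterbi <- function(x, t, pi, A, p) {
  paths <- all_paths(length(x))
  lp <- apply(paths, 1, path_log_prob, x = x, t = t, pi = pi, A = A, p = p)
  best <- which(lp > max(lp) - 1e-12)
  list(paths = paths[best, , drop = FALSE], log_prob = max(lp))
}

# Benjamini-Hochberg by the step-up definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  adj[o] <- rev(cummin(rev(sorted)))
  pmin(adj, 1)
}

# AUC as the Mann-Whitney pairwise-comparison statistic
auc_pairwise <- function(scores, truth) {
  sp <- scores[truth]
  sn <- scores[!truth]
  tot <- 0
  for (s in sp) tot <- tot + sum(s > sn) + 0.5 * sum(s == sn)
  tot / (length(sp) * length(sn))
}

# random valid HMM parameter draw for property tests
rand_params <- function() {
  A <- matrix(runif(4, 0.05, 0.95), 2, 2)
  A <- A / rowSums(A)
  p <- sort(runif(2, 0.05, 0.95))
  if (p[2] - p[1] < 0.02) p <- c(p[1], min(p[1] + 0.1, 0.95))
  hmm_params(pi = runif(1, 0.05, 0.95), A = A, p = p)
}

# random small count chain
rand_counts <- function(N, id = "g") {
  t <- rpois(N, 12)
  x <- rbinom(N, t, runif(1, 0.2, 0.8))
  bin_counts(id, x, t - x)
}

# prior marginal state distribution of the chain at every position
chain_marginals <- function(N, pi, A) {
  m <- matrix(0, N, 2)
  m[1, ] <- c(pi, 1 - pi)
  if (N > 1) for (n in 2:N) m[n, ] <- m[n - 1, ] %*% A
  m
}
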