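#' @useDynLib meripHMM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dbinom pbinom pnorm p.adjust quantile rbinom rpois runif sd
NULL

P_CLAMP <- c(1e-6, 1 - 1e-6)

#' Construct the parameter set of the two-state methylation HMM
#'
#' The chain has states 1 (unmethylated) and 2 (methylated). `pi` is the
#' probability that the first bin of a gene is unmethylated; `A[j, k]` is the
#' probability of moving from state j to state k between adjacent bins; `p`
#' holds the binomial success probabilities (expected IP fraction of the
#' combined IP + control count in a bin) for the two states. Identifiability
#' requires `p[1] < p[2]`: the methylated state is, by definition, the one
#' with the higher IP fraction.
#'
#' @param pi initial probability of the unmethylated state, in `[0, 1]`.
#' @param A 2x2 row-stochastic transition matrix.
#' @param p length-2 vector of binomial success probabilities, `0 < p1 < p2 < 1`.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(pi, A, p) {
  A <- matrix(as.numeric(A), 2, 2)
  p <- as.numeric(p)
  stopifnot(length(pi) == 1, pi >= 0, pi <= 1,
            length(p) == 2, all(p > 0), all(p < 1))
  if (p[1] >= p[2]) {
    stop("'p' must be ordered p1 < p2 (state 2 is the methylated, IP-enriched state)")
  }
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-12)) {
    stop("rows of 'A' must be non-negative and sum to 1")
  }
  structure(list(pi = pi, A = A, p = p), class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("Two-state binomial-emission HMM parameters\n")
  cat(sprintf("  pi (P(z1 = unmethylated)): %.4f\n", x$pi))
  cat(sprintf("  A: [%.4f %.4f; %.4f %.4f]\n",
              x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2]))
  cat(sprintf("  p: (%.4f, %.4f)\n", x$p[1], x$p[2]))
  invisible(x)
}

#' Binomial emission log-probability
#'
#' Log-probability of observing `x` IP reads out of `t` combined reads in a
#' bin whose state has IP fraction `p`, including the binomial coefficient.
#' A bin with `t = 0` is uninformative and returns 0 (probability 1) for any
#' state, so empty bins stay in the chain and carry transition information.
#'
#' @param x IP read count(s).
#' @param t combined IP + control count(s), `x <= t`.
#' @param p binomial success probability in (0, 1).
#' @return log-probabilities, vectorized over `x`/`t`.
#' @export
emission_log_prob <- function(x, t, p) {
  if (any(x < 0) || any(x > t)) stop("'x' must satisfy 0 <= x <= t")
  p <- min(max(p, P_CLAMP[1]), P_CLAMP[2])
  dbinom(x, t, p, log = TRUE)
}

# N x 2 emission log-prob matrix for concatenated bins
emission_matrix <- function(x, t, p) {
  cbind(emission_log_prob(x, t, p[1]), emission_log_prob(x, t, p[2]))
}

#' Forward-backward posteriors for one gene
#'
#' Runs the scaled forward-backward recursions and returns the marginal
#' posteriors `gamma[n, k] = P(z_n = k | x, theta)`, the pairwise posteriors
#' `epsilon[n, j, k] = P(z_n = j, z_{n+1} = k | x, theta)` for the N-1
#' transitions, and the data log-likelihood (binomial coefficients included)
#' accumulated from the scaling constants.
#'
#' @param counts a [bin_counts] object.
#' @param params an [hmm_params] object.
#' @return an object of class `hmm_posteriors` with elements `gamma`
#'   (N x 2), `epsilon` ((N-1) x 2 x 2) and `log_likelihood`.
#' @export
forward_backward <- function(counts, params) {
  stopifnot(inherits(counts, "bin_counts"), inherits(params, "hmm_params"))
  N <- length(counts$x)
  logB <- emission_matrix(counts$x, counts$t, params$p)
  res <- .fb_cpp(logB, N, c(params$pi, 1 - params$pi), params$A)
  eps <- array(res$epsilon, dim = c(max(N - 1L, 0L), 2L, 2L))
  structure(list(gamma = res$gamma, epsilon = eps,
                 log_likelihood = res$loglik[1]),
            class = "hmm_posteriors")
}

# forward-backward over a whole collection, one C++ call;
# returns pooled sufficient statistics along with the stacked gamma
fb_all <- function(count_sets, params) {
  lens <- vapply(count_sets, function(cs) length(cs$x), integer(1))
  x <- unlist(lapply(count_sets, `[[`, "x"), use.names = FALSE)
  t <- unlist(lapply(count_sets, `[[`, "t"), use.names = FALSE)
  logB <- emission_matrix(x, t, params$p)
  res <- .fb_cpp(logB, lens, c(params$pi, 1 - params$pi), params$A)
  first <- cumsum(c(1L, lens[-length(lens)]))
  g1 <- res$gamma[first, , drop = FALSE]
  list(gamma = res$gamma, lens = lens, x = x, t = t,
       loglik = sum(res$loglik),
       gamma1_sum = colSums(g1),
       eps_sum = matrix(colSums(res$epsilon), 2, 2),
       px_num = colSums(res$gamma * x),
       px_den = colSums(res$gamma * t))
}

# shared M-step closed forms from pooled sufficient statistics
m_step_from_stats <- function(gamma1_sum, eps_sum, px_num, px_den,
                              prev = NULL) {
  pi <- gamma1_sum[1] / sum(gamma1_sum)
  A <- eps_sum
  for (j in 1:2) {
    rs <- sum(eps_sum[j, ])
    if (rs <= 0) {  # state never left from: no transition information
      if (is.null(prev)) {
        stop("no transitions out of state ", j, " and no previous value to keep")
      }
      warning("state ", j, " has no outgoing transition mass; keeping previous A row")
      A[j, ] <- prev$A[j, ]
    } else {
      A[j, ] <- eps_sum[j, ] / rs
    }
  }
  p <- numeric(2)
  for (k in 1:2) {
    if (px_den[k] <= 0) {
      if (is.null(prev)) {
        stop("state ", k, " has zero posterior mass and no previous value to keep")
      }
      warning("state ", k, " never visited; keeping previous p", k)
      p[k] <- prev$p[k]
    } else {
      p[k] <- px_num[k] / px_den[k]
    }
  }
  p <- pmin(pmax(p, P_CLAMP[1]), P_CLAMP[2])
  if (p[1] > p[2]) {  # relabel states so state 2 is the IP-enriched one
    p <- rev(p)
    pi <- 1 - pi
    A <- A[2:1, 2:1]
  }
  if (p[1] == p[2]) p[2] <- min(p[2] + 1e-9, P_CLAMP[2])
  hmm_params(pi = pi, A = A, p = p)
}

#' M-step parameter update from posteriors
#'
#' Re-estimates `pi`, `A` and `p` from the expected sufficient statistics of
#' one or more genes sharing a single parameter set. `pi` is re-estimated
#' from the first-bin posteriors, `A` from row-normalized pooled pairwise
#' posteriors, and each `p_k` as the posterior-weighted IP fraction
#' `sum(gamma_k * x) / sum(gamma_k * t)` pooled over genes. If the update
#' leaves `p1 > p2` the state labels are swapped throughout (identifiability).
#'
#' @param posterior_sets list of [forward_backward] results, one per gene.
#' @param count_sets list of [bin_counts], aligned with `posterior_sets`.
#' @param params optional previous [hmm_params]; a state with zero posterior
#'   mass keeps its previous `p_k` (with a warning) instead of failing.
#' @return an [hmm_params] object.
#' @export
m_step <- function(posterior_sets, count_sets, params = NULL) {
  if (inherits(posterior_sets, "hmm_posteriors")) posterior_sets <- list(posterior_sets)
  if (inherits(count_sets, "bin_counts")) count_sets <- list(count_sets)
  stopifnot(length(posterior_sets) == length(count_sets))
  g1 <- c(0, 0); es <- matrix(0, 2, 2); num <- c(0, 0); den <- c(0, 0)
  for (i in seq_along(posterior_sets)) {
    po <- posterior_sets[[i]]; cs <- count_sets[[i]]
    g1 <- g1 + po$gamma[1, ]
    if (dim(po$epsilon)[1] > 0) es <- es + apply(po$epsilon, c(2, 3), sum)
    num <- num + colSums(po$gamma * cs$x)
    den <- den + colSums(po$gamma * cs$t)
  }
  m_step_from_stats(g1, es, num, den, prev = params)
}

# default initialization: neutral sticky chain, p1/p2 from the quartiles of
# the observed per-bin IP fraction (respects the ordering constraint)
default_init <- function(x, t) {
  frac <- x[t > 0] / t[t > 0]
  p <- unname(quantile(frac, c(0.25, 0.75), names = FALSE))
  p <- pmin(pmax(p, 0.05), 0.95)
  if (p[2] - p[1] < 0.05) {
    mid <- (p[1] + p[2]) / 2
    p <- c(max(mid - 0.05, 0.01), min(mid + 0.05, 0.99))
  }
  hmm_params(pi = 0.5, A = matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE), p = p)
}

#' Fit the HMM by multi-sequence EM
#'
#' Alternates forward-backward (E step) and the closed-form M step with one
#' parameter set shared across all genes; each gene is an independent chain
#' restarting from the initial distribution. Iteration stops when the
#' relative change of the data log-likelihood drops below `tol` or after
#' `max_iter` iterations. The recorded trace is non-decreasing (up to
#' floating-point slack), as EM guarantees.
#'
#' @param count_sets a list of [bin_counts] objects (or a single one).
#' @param init optional [hmm_params] starting point; by default `pi = 0.5`,
#'   a sticky transition matrix, and `p1`/`p2` at the 25th/75th percentile of
#'   the observed per-bin IP fraction.
#' @param tol relative log-likelihood change below which EM stops.
#' @param max_iter maximum number of EM iterations.
#' @param verbose print per-iteration log-likelihood.
#' @return an object of class `hmm_fit`: `params`, `loglik_trace`,
#'   `n_iter`, `converged`.
#' @export
em_fit <- function(count_sets, init = NULL, tol = 1e-6, max_iter = 100,
                   verbose = FALSE) {
  if (inherits(count_sets, "bin_counts")) count_sets <- list(count_sets)
  stopifnot(length(count_sets) >= 1, max_iter >= 1)
  x <- unlist(lapply(count_sets, `[[`, "x"), use.names = FALSE)
  t <- unlist(lapply(count_sets, `[[`, "t"), use.names = FALSE)
  if (all(t == 0)) stop("no informative bins: all combined counts are zero")
  params <- if (is.null(init)) default_init(x, t) else init
  stopifnot(inherits(params, "hmm_params"))
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    st <- fb_all(count_sets, params)
    trace[it] <- st$loglik
    if (verbose) message(sprintf("EM iter %d: loglik = %.6f", it, st$loglik))
    params_new <- m_step_from_stats(st$gamma1_sum, st$eps_sum,
                                    st$px_num, st$px_den, prev = params)
    if (it > 1 && abs(trace[it] - trace[it - 1]) < tol * abs(trace[it])) {
      converged <- TRUE
      params <- params_new
      break
    }
    params <- params_new
  }
  structure(list(params = params, loglik_trace = trace,
                 n_iter = length(trace), converged = converged),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("HMM fit: %d EM iterations, %s (loglik %.4f)\n", x$n_iter,
              if (x$converged) "converged" else "max_iter reached",
              x$loglik_trace[x$n_iter]))
  print(x$params)
  invisible(x)
}

#' Viterbi MAP decoding of the methylation path
#'
#' Returns the most probable state sequence for one gene under the fitted
#' parameters, by log-space dynamic programming. Ties are broken toward
#' state 1 (unmethylated), i.e. peak calling is conservative.
#'
#' @param counts a [bin_counts] object.
#' @param params an [hmm_params] object.
#' @return integer vector of states in `{1, 2}`, one per bin.
#' @export
viterbi <- function(counts, params) {
  stopifnot(inherits(counts, "bin_counts"), inherits(params, "hmm_params"))
  logB <- emission_matrix(counts$x, counts$t, params$p)
  pi2 <- pmax(c(params$pi, 1 - params$pi), 1e-300)
  .viterbi_cpp(logB, length(counts$x), log(pi2),
               log(pmax(params$A, 1e-300)))
}

# decode all genes with one C++ call
viterbi_all <- function(count_sets, params) {
  lens <- vapply(count_sets, function(cs) length(cs$x), integer(1))
  x <- unlist(lapply(count_sets, `[[`, "x"), use.names = FALSE)
  t <- unlist(lapply(count_sets, `[[`, "t"), use.names = FALSE)
  logB <- emission_matrix(x, t, params$p)
  pi2 <- pmax(c(params$pi, 1 - params$pi), 1e-300)
  path <- .viterbi_cpp(logB, lens, log(pi2), log(pmax(params$A, 1e-300)))
  split(path, rep(seq_along(lens), lens))
}

#' Write fitted HMM parameters to a flat key-value text file
#'
#' @param params an [hmm_params] object.
#' @param path output file.
#' @export
write_hmm_params <- function(params, path) {
  stopifnot(inherits(params, "hmm_params"))
  lines <- c(
    sprintf("pi\t%.17g", params$pi),
    sprintf("A11\t%.17g", params$A[1, 1]), sprintf("A12\t%.17g", params$A[1, 2]),
    sprintf("A21\t%.17g", params$A[2, 1]), sprintf("A22\t%.17g", params$A[2, 2]),
    sprintf("p1\t%.17g", params$p[1]), sprintf("p2\t%.17g", params$p[2]))
  writeLines(lines, path)
  invisible(path)
}

#' Read HMM parameters from a key-value file written by [write_hmm_params]
#'
#' @param path input file.
#' @return an [hmm_params] object.
#' @export
read_hmm_params <- function(path) {
  kv <- utils::read.table(path, sep = "\t", col.names = c("key", "value"),
                          colClasses = c("character", "numeric"))
  v <- stats::setNames(kv$value, kv$key)
  hmm_params(pi = v[["pi"]],
             A = matrix(c(v[["A11"]], v[["A21"]], v[["A12"]], v[["A22"]]), 2, 2),
             p = c(v[["p1"]], v[["p2"]]))
}
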