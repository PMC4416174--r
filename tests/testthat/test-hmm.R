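test_that("binomial emission log-probabilities match closed forms", {
  expect_identical(emission_log_prob(0, 0, 0.5), 0)
  expect_equal(emission_log_prob(1, 2, 0.5), log(0.5))
  # C(10,7) 0.8^7 0.2^3 = 120 * 0.8^7 * 0.2^3
  expect_equal(emission_log_prob(7, 10, 0.8), log(120 * 0.8^7 * 0.2^3))
  expect_error(emission_log_prob(3, 2, 0.5), "x")
})

test_that("hmm_params enforces its invariants", {
  expect_error(hmm_params(0.5, matrix(c(0.6, 0.4, 0.5, 0.6), 2, byrow = TRUE),
                          c(0.2, 0.8)), "sum to 1")
  expect_error(hmm_params(0.5, diag(2), c(0.8, 0.2)), "ordered")
  expect_error(hmm_params(1.5, diag(2), c(0.2, 0.8)))
  p <- hmm_params(0.2, matrix(c(0.7, 0.3, 0.1, 0.9), 2, byrow = TRUE),
                  c(0.2, 0.8))
  expect_s3_class(p, "hmm_params")
})

test_that("single-bin posterior reduces to direct Bayes", {
  params <- hmm_params(0.2, matrix(c(0.7, 0.3, 0.1, 0.9), 2, byrow = TRUE),
                       c(0.2, 0.8))
  po <- forward_backward(bin_counts("g", x = 3, y = 1), params)
  # prior (0.2, 0.8); likelihoods dbinom(3, 4, p): 0.0256 and 0.4096
  expect_equal(po$gamma[1, ], c(0.2 * 0.0256, 0.8 * 0.4096) /
                 (0.2 * 0.0256 + 0.8 * 0.4096), tolerance = 1e-12)
  expect_equal(po$gamma[1, ], c(0.01538, 0.98462), tolerance = 1e-4)
  expect_equal(po$log_likelihood, log(0.2 * 0.0256 + 0.8 * 0.4096))
})

test_that("empty bins are uninformative: posteriors follow the prior chain", {
  params <- hmm_params(0.2, matrix(c(0.7, 0.3, 0.1, 0.9), 2, byrow = TRUE),
                       c(0.2, 0.8))
  po <- forward_backward(bin_counts("g", c(0, 0), c(0, 0)), params)
  expect_equal(po$gamma[2, ], c(0.22, 0.78), tolerance = 1e-12)
  expect_equal(po$gamma[1, ], c(0.2, 0.8), tolerance = 1e-12)
  # degenerate-emission limit: p1 ~= p2 gives prior marginals regardless of counts
  params_eq <- hmm_params(0.3, matrix(c(0.6, 0.4, 0.2, 0.8), 2, byrow = TRUE),
                          c(0.5, 0.5 + 1e-12))
  cs <- bin_counts("g", c(3, 8, 1, 6), c(5, 2, 7, 4))
  po_eq <- forward_backward(cs, params_eq)
  expect_equal(po_eq$gamma, chain_marginals(4, 0.3, params_eq$A),
               tolerance = 1e-6)
})

test_that("forward-backward matches exhaustive enumeration on random chains", {
  set.seed(421)
  for (rep in 1:100) {
    N <- sample(1:10, 1)
    params <- rand_params()
    cs <- rand_counts(N)
    po <- forward_backward(cs, params)
    oracle <- enum_posteriors(cs$x, cs$t, params$pi, params$A, params$p)
    expect_equal(po$gamma, oracle$gamma, tolerance = 1e-9)
    expect_equal(po$epsilon, oracle$epsilon, tolerance = 1e-9)
    expect_equal(po$log_likelihood, oracle$log_likelihood, tolerance = 1e-9)
  }
})

test_that("posterior consistency invariants hold on every E step", {
  set.seed(99)
  for (rep in 1:20) {
    N <- sample(2:40, 1)
    params <- rand_params()
    po <- forward_backward(rand_counts(N), params)
    expect_equal(rowSums(po$gamma), rep(1, N), tolerance = 1e-9)
    # both marginalizations of epsilon
    expect_equal(apply(po$epsilon, c(1, 3), sum), po$gamma[-1, , drop = FALSE],
                 tolerance = 1e-9)
    expect_equal(apply(po$epsilon, c(1, 2), sum), po$gamma[-N, , drop = FALSE],
                 tolerance = 1e-9)
  }
})

test_that("M-step closed forms reduce to pooled ratios", {
  params <- hmm_params(0.2, matrix(c(0.7, 0.3, 0.1, 0.9), 2, byrow = TRUE),
                       c(0.2, 0.8))
  # all mass on state 2: p2 = (3+5)/(10+10)
  po <- structure(list(gamma = matrix(c(0, 0, 1, 1), 2, 2),
                       epsilon = array(c(0, 0, 0, 1), c(1, 2, 2)),
                       log_likelihood = 0), class = "hmm_posteriors")
  cs <- bin_counts("g", c(3, 5), c(7, 5))
  w <- capture_warnings(up <- m_step(po, cs, params = params))
  expect_true(any(grepl("never visited", w)))
  expect_equal(up$p[2], 8 / 20)
  expect_equal(up$p[1], params$p[1])  # unvisited state keeps its old value
  # pi comes straight from the first-bin posterior
  po2 <- structure(list(gamma = matrix(c(0.3, 0.4, 0.7, 0.6), 2, 2),
                        epsilon = array(c(1, 1, 1, 1) / 4, c(1, 2, 2)),
                        log_likelihood = 0), class = "hmm_posteriors")
  cs2 <- bin_counts("g", c(8, 8), c(2, 2))  # flat enrichment: no label swap
  up2 <- m_step(po2, cs2, params = params)
  expect_equal(up2$pi, 0.3)
  # rows of A are normalized epsilon totals: (4,1) -> (0.8, 0.2)
  po3 <- structure(list(gamma = matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2),
                        epsilon = array(c(4, 2, 1, 3) / 10, c(1, 2, 2)),
                        log_likelihood = 0), class = "hmm_posteriors")
  up3 <- m_step(po3, cs2, params = params)
  expect_equal(up3$A[1, ], c(0.8, 0.2), ignore_attr = TRUE)
})

test_that("M-step relabels states so p1 < p2 always holds", {
  params <- hmm_params(0.3, matrix(c(0.7, 0.3, 0.1, 0.9), 2, byrow = TRUE),
                       c(0.2, 0.8))
  # posterior mass arranged so that state 1 looks IP-enriched pre-swap
  po <- structure(list(gamma = matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2),
                       epsilon = array(c(0.8, 0.05, 0.1, 0.05), c(1, 2, 2)),
                       log_likelihood = 0), class = "hmm_posteriors")
  cs <- bin_counts("g", c(9, 1), c(1, 9))
  up <- m_step(po, cs, params = params)
  expect_lt(up$p[1], up$p[2])
  expect_equal(up$p[2], (0.9 * 9 + 0.2 * 1) / (0.9 * 10 + 0.2 * 10))
  set.seed(7)
  for (rep in 1:10) {
    cs <- rand_counts(sample(2:15, 1))
    pr <- rand_params()
    up <- m_step(forward_backward(cs, pr), cs, params = pr)
    expect_lt(up$p[1], up$p[2])
  }
})

test_that("EM iterates the stated number of times and never decreases", {
  set.seed(5)
  cs <- lapply(1:30, function(i) rand_counts(20, sprintf("g%d", i)))
  fit <- em_fit(cs, tol = 0, max_iter = 5)
  expect_length(fit$loglik_trace, 5)
  expect_identical(fit$n_iter, 5L)
  expect_false(fit$converged)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  fit2 <- em_fit(cs, tol = 1e-6, max_iter = 100)
  expect_true(fit2$converged)
  expect_true(all(diff(fit2$loglik_trace) >= -1e-8))
})

test_that("EM restarted at its own solution stops immediately", {
  set.seed(6)
  sim <- simulate_hmm_counts(100, c(10, 20), seed = 6)
  fit <- em_fit(sim$count_sets, tol = 1e-8)
  refit <- em_fit(sim$count_sets, init = fit$params, tol = 1e-8)
  expect_lte(refit$n_iter, 2)
})

test_that("EM refuses data with no informative bins", {
  cs <- list(bin_counts("g1", c(0, 0), c(0, 0)))
  expect_error(em_fit(cs), "no informative bins")
})

test_that("EM recovers generating parameters from a large simulation", {
  sim <- simulate_hmm_counts(3000, c(10, 30),
                             params = hmm_params(0.2,
                               matrix(c(0.7, 0.3, 0.1, 0.9), 2, byrow = TRUE),
                               c(0.3, 0.8)),
                             seed = 314)
  fit <- em_fit(sim$count_sets)
  expect_lt(abs(fit$params$pi - 0.2), 0.03)  # ~4 sd for 3000 Bernoulli draws
  expect_true(all(abs(fit$params$A -
                        matrix(c(0.7, 0.3, 0.1, 0.9), 2, byrow = TRUE)) < 0.02))
  expect_true(all(abs(fit$params$p - c(0.3, 0.8)) < 0.01))
})

test_that("Viterbi matches per-bin argmax under uniform transitions", {
  params <- hmm_params(0.5, matrix(0.5, 2, 2), c(0.1, 0.9))
  path <- viterbi(bin_counts("g", c(9, 0, 8), c(1, 10, 2)), params)
  expect_identical(path, c(2L, 1L, 2L))
})

test_that("Viterbi finds the exhaustive MAP path", {
  params <- hmm_params(0.2, matrix(c(0.7, 0.3, 0.1, 0.9), 2, byrow = TRUE),
                       c(0.2, 0.8))
  cs <- bin_counts("g", c(1, 5, 9), c(9, 5, 1))
  expect_identical(viterbi(cs, params), c(1L, 2L, 2L))
  set.seed(88)
  for (rep in 1:100) {
    N <- sample(1:10, 1)
    pr <- rand_params()
    cs <- rand_counts(N)
    path <- viterbi(cs, pr)
    oracle <- enum_viterbi(cs$x, cs$t, pr$pi, pr$A, pr$p)
    # the decoded path must attain the maximal joint probability
    expect_equal(path_log_prob(path, cs$x, cs$t, pr$pi, pr$A, pr$p),
                 oracle$log_prob, tolerance = 1e-9)
    if (nrow(oracle$paths) == 1) {
      expect_identical(path, as.integer(oracle$paths[1, ]),
                       ignore_attr = TRUE)
    }
  }
})

test_that("fitted parameters survive a file round trip", {
  pr <- hmm_params(0.2345, matrix(c(0.71, 0.29, 0.12, 0.88), 2, byrow = TRUE),
                   c(0.213, 0.787))
  f <- withr::local_tempfile(fileext = ".txt")
  write_hmm_params(pr, f)
  back <- read_hmm_params(f)
  expect_equal(back$pi, pr$pi)
  expect_equal(back$A, pr$A, ignore_attr = TRUE)
  expect_equal(back$p, pr$p)
})
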