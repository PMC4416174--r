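#' Simulator configuration
#'
#' Defaults reproduce the validation study's generative process: 5000 genes
#' with lengths uniform on 500-3000 nt, 100-nt bins, methylation states from
#' a two-state Markov chain with `A = [[0.7, 0.3], [0.1, 0.9]]` and initial
#' unmethylated probability `pi = 0.2`; per gene one control Poisson rate
#' `lambda_ctrl ~ U(5, 20)` constant across bins and states; per bin an IP
#' rate `lambda_IP ~ U(lambda_ctrl, 100)` when methylated and
#' `U(0, lambda_ctrl)` when unmethylated; counts Poisson at unit sequencing
#' depth in both samples.
#'
#' @param n_genes number of genes.
#' @param gene_length_range min/max transcript length in nt (uniform draw).
#' @param bin_size bin width in nt.
#' @param A 2x2 row-stochastic transition matrix, states (unmeth, meth).
#' @param pi initial probability of the unmethylated state.
#' @param lambda_ctrl_range control Poisson rate interval, per-gene uniform.
#' @param lambda_ip_methylated,lambda_ip_unmethylated IP-rate intervals as
#'   length-2 vectors where `NA` stands for the gene's `lambda_ctrl` draw.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000, gene_length_range = c(500, 3000),
                       bin_size = 100,
                       A = matrix(c(0.7, 0.3, 0.1, 0.9), 2, 2, byrow = TRUE),
                       pi = 0.2, lambda_ctrl_range = c(5, 20),
                       lambda_ip_methylated = c(NA, 100),
                       lambda_ip_unmethylated = c(0, NA),
                       seed = NULL) {
  A <- matrix(as.numeric(A), 2, 2)
  stopifnot(n_genes >= 0, bin_size >= 1,
            gene_length_range[1] <= gene_length_range[2],
            lambda_ctrl_range[1] < lambda_ctrl_range[2],
            pi >= 0, pi <= 1,
            all(abs(rowSums(A) - 1) < 1e-12), all(A >= 0))
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_range = gene_length_range, bin_size = bin_size,
                 A = A, pi = pi, lambda_ctrl_range = lambda_ctrl_range,
                 lambda_ip_methylated = lambda_ip_methylated,
                 lambda_ip_unmethylated = lambda_ip_unmethylated,
                 seed = seed),
            class = "sim_config")
}

# draw a state path: z1 = 1 w.p. pi, transitions by A
sim_state_path <- function(n, pi, A) {
  z <- integer(n)
  z[1] <- if (runif(1) < pi) 1L else 2L
  if (n > 1) {
    u <- runif(n - 1)
    for (i in 2:n) z[i] <- if (u[i - 1] < A[z[i - 1], 1]) 1L else 2L
  }
  z
}

# IP rate for one bin, interval NA slots filled with lambda_ctrl
sim_ip_rate <- function(range, lambda_ctrl) {
  lo <- if (is.na(range[1])) lambda_ctrl else range[1]
  hi <- if (is.na(range[2])) lambda_ctrl else range[2]
  runif(length(lambda_ctrl), lo, hi)
}

#' Simulate a truth-labelled MeRIP-seq bin-count dataset
#'
#' Generates per-gene methylation paths and Poisson IP/control counts under
#' the configured rates (see [sim_config]). Fully reproducible from the
#' seed; gene order is deterministic.
#'
#' @param config a [sim_config].
#' @param seed overrides `config$seed` when given.
#' @return an object of class `sim_dataset`: `count_sets` (named list of
#'   [bin_counts]), `truth` (named list of integer state vectors, 2 =
#'   methylated), `lambda_ctrl` (per-gene draws), `config`, `seed`.
#' @export
simulate_merip <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_genes
  ids <- sprintf("gene_%05d", seq_len(n))
  count_sets <- vector("list", n)
  truth <- vector("list", n)
  lam_ctrl <- numeric(n)
  if (n > 0) {
    lens <- config$gene_length_range[1] +
      sample.int(config$gene_length_range[2] - config$gene_length_range[1] + 1L,
                 n, replace = TRUE) - 1L
    for (g in seq_len(n)) {
      N <- as.integer(ceiling(lens[g] / config$bin_size))
      z <- sim_state_path(N, config$pi, config$A)
      lc <- runif(1, config$lambda_ctrl_range[1], config$lambda_ctrl_range[2])
      lam_ip <- numeric(N)
      meth <- z == 2L
      if (any(meth)) {
        lam_ip[meth] <- sim_ip_rate(config$lambda_ip_methylated,
                                    rep(lc, sum(meth)))
      }
      if (any(!meth)) {
        lam_ip[!meth] <- sim_ip_rate(config$lambda_ip_unmethylated,
                                     rep(lc, sum(!meth)))
      }
      count_sets[[g]] <- bin_counts(ids[g], rpois(N, lam_ip), rpois(N, lc))
      truth[[g]] <- z
      lam_ctrl[g] <- lc
    }
  }
  names(count_sets) <- ids
  names(truth) <- ids
  structure(list(count_sets = count_sets, truth = truth,
                 lambda_ctrl = lam_ctrl, config = config, seed = seed),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  nb <- sum(vapply(x$truth, length, integer(1)))
  cat(sprintf("Simulated MeRIP-seq dataset: %d genes, %d bins, seed %s\n",
              length(x$count_sets), nb,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' True peak regions of a simulated dataset
#'
#' A true peak is a maximal run of methylated bins in the simulated state
#' path; indices are 0-based half-open.
#'
#' @param dataset a `sim_dataset` from [simulate_merip].
#' @return data frame with `gene_id`, `bin_start`, `bin_end`.
#' @export
truth_regions <- function(dataset) {
  stopifnot(inherits(dataset, "sim_dataset"))
  res <- lapply(names(dataset$truth), function(g) {
    r <- rle(dataset$truth[[g]] == 2L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- which(r$values)
    if (length(keep) == 0) return(NULL)
    data.frame(gene_id = g, bin_start = starts[keep], bin_end = ends[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), bin_start = integer(0),
                      bin_end = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Simulate directly from the binomial-emission HMM
#'
#' Generates count sets whose emission law is exactly the fitted model:
#' state paths from `params`, per-bin totals `t_n ~ Poisson(depth)` with a
#' per-gene depth uniform on `depth_range`, and `x_n ~ Binomial(t_n, p_z)`.
#' Because the true `p1`, `p2` are well-defined here, this generator is the
#' one used for parameter-recovery checks.
#'
#' @param n_genes number of chains.
#' @param n_bins_range min/max bins per chain (uniform integer draw).
#' @param params true [hmm_params].
#' @param depth_range per-gene mean total count range.
#' @param seed integer seed or `NULL`.
#' @return list with `count_sets` and `truth`, as in [simulate_merip].
#' @export
simulate_hmm_counts <- function(n_genes, n_bins_range = c(5, 30),
                                params = hmm_params(0.2,
                                  matrix(c(0.7, 0.3, 0.1, 0.9), 2, byrow = TRUE),
                                  c(0.3, 0.8)),
                                depth_range = c(15, 60), seed = NULL) {
  stopifnot(inherits(params, "hmm_params"))
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("chain_%05d", seq_len(n_genes))
  count_sets <- vector("list", n_genes)
  truth <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    N <- n_bins_range[1] +
      sample.int(n_bins_range[2] - n_bins_range[1] + 1L, 1) - 1L
    z <- sim_state_path(N, params$pi, params$A)
    t <- rpois(N, runif(1, depth_range[1], depth_range[2]))
    x <- rbinom(N, t, params$p[z])
    count_sets[[g]] <- bin_counts(ids[g], x, t - x)
    truth[[g]] <- z
  }
  names(count_sets) <- ids
  names(truth) <- ids
  list(count_sets = count_sets, truth = truth, params = params, seed = seed)
}

#' Simulate replicate worked-example genes (10 methylated bins in 100)
#'
#' Each replicate is one 100-bin gene whose truth has a single contiguous
#' block of `n_meth` methylated bins at a uniformly random position, with
#' IP/control counts drawn at the standard simulator rates. This is the
#' setting used to compare false-positive rates at matched sensitivity.
#'
#' @param n_reps number of replicate genes.
#' @param n_bins bins per gene.
#' @param n_meth methylated bins per gene (one contiguous block).
#' @param lambda_ctrl_range,lambda_ip_max rate settings as in [sim_config].
#' @param seed integer seed or `NULL`.
#' @return list with `count_sets` and `truth` (state vectors, 2 = methylated).
#' @export
simulate_worked_example <- function(n_reps = 200, n_bins = 100, n_meth = 10,
                                    lambda_ctrl_range = c(5, 20),
                                    lambda_ip_max = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("rep_%04d", seq_len(n_reps))
  count_sets <- vector("list", n_reps)
  truth <- vector("list", n_reps)
  for (g in seq_len(n_reps)) {
    z <- rep(1L, n_bins)
    s <- sample(0:(n_bins - n_meth), 1)
    z[(s + 1):(s + n_meth)] <- 2L
    lc <- runif(1, lambda_ctrl_range[1], lambda_ctrl_range[2])
    lam_ip <- ifelse(z == 2L, runif(n_bins, lc, lambda_ip_max),
                     runif(n_bins, 0, lc))
    count_sets[[g]] <- bin_counts(ids[g], rpois(n_bins, lam_ip), rpois(n_bins, lc))
    truth[[g]] <- z
  }
  names(count_sets) <- ids
  names(truth) <- ids
  list(count_sets = count_sets, truth = truth, seed = seed)
}
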