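#' Independent-bin exact binomial test (baseline caller)
#'
#' The comparison baseline treats every bin independently: a pooled null IP
#' fraction `p0 = sum(x) / sum(t)` over all bins, then per bin the one-sided
#' exact binomial tail `P(X >= x_n | t_n, p0)`. The bin score is `-ln p`.
#' Empty bins (`t = 0`) get `p = 1`. This is a deliberately bin-independent
#' caller: it ignores the spatial correlation the HMM exploits.
#'
#' @param count_sets list of [bin_counts] (or a single one).
#' @return data frame with one row per bin: `gene_id`, `bin` (1-based),
#'   `x`, `t`, `p_value`, `score`; attribute `p0` carries the pooled null.
#' @export
independent_bin_test <- function(count_sets) {
  if (inherits(count_sets, "bin_counts")) count_sets <- list(count_sets)
  x <- unlist(lapply(count_sets, `[[`, "x"), use.names = FALSE)
  t <- unlist(lapply(count_sets, `[[`, "t"), use.names = FALSE)
  if (sum(t) == 0) stop("all bins empty: pooled null proportion undefined")
  p0 <- sum(x) / sum(t)
  p <- pbinom(x - 1, t, p0, lower.tail = FALSE)  # P(X >= x)
  p[t == 0] <- 1
  out <- data.frame(
    gene_id = rep(vapply(count_sets, `[[`, character(1), "gene_id"),
                  vapply(count_sets, function(cs) length(cs$x), integer(1))),
    bin = unlist(lapply(count_sets, function(cs) seq_along(cs$x)),
                 use.names = FALSE),
    x = x, t = t, p_value = p, score = -log(pmax(p, 1e-300)),
    stringsAsFactors = FALSE)
  attr(out, "p0") <- p0
  out
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique score values as thresholds (call positive when
#' `score >= threshold`); tied scores move together, so the trapezoid AUC
#' equals the rank-average (Mann-Whitney) statistic.
#'
#' @param scores numeric score per instance (higher = more peak-like).
#' @param truth logical (or coercible) positive-class labels.
#' @return an object of class `roc_result`: `thresholds`, `tpr`, `fpr`
#'   (starting at (0,0), ending at (1,1)), and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  P <- sum(truth); N <- sum(!truth)
  if (P == 0 || N == 0) stop("both classes must be present in 'truth'")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- truth[o]
  last <- which(c(s[-1] != s[-length(s)], TRUE))  # end of each tie group
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, s[last]), tpr = unname(tpr),
                 fpr = unname(fpr), auc = unname(auc)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d thresholds, AUC = %.4f\n", length(x$thresholds), x$auc))
  invisible(x)
}

#' False-positive rate at a matched sensitivity
#'
#' Sets the calling threshold at the score of the `ceiling(sens * P)`-th
#' best positive (so at least that fraction of true positives is called)
#' and reports how many negatives score at or above it.
#'
#' @param scores per-instance scores.
#' @param truth logical positive labels.
#' @param sensitivity fraction of positives that must be recovered.
#' @return list: `threshold`, `n_tp`, `n_fp`, `fpr` (fraction of negatives).
#' @export
fpr_at_sensitivity <- function(scores, truth, sensitivity = 0.8) {
  truth <- as.logical(truth)
  P <- sum(truth)
  stopifnot(P > 0, sum(!truth) > 0, sensitivity > 0, sensitivity <= 1)
  k <- ceiling(sensitivity * P)
  thr <- sort(scores[truth], decreasing = TRUE)[k]
  called <- scores >= thr
  list(threshold = thr, n_tp = sum(called & truth),
       n_fp = sum(called & !truth), fpr = mean(called[!truth]))
}

#' Compare the HMM caller against the independent-bin baseline
#'
#' Fits the shared-parameter HMM to the dataset's counts, scores every bin
#' by its posterior probability of the methylated state, scores the same
#' bins with the independent binomial test, and computes bin-level ROC
#' curves for both against the simulated truth.
#'
#' @param dataset a `sim_dataset` (or any list with `count_sets` and
#'   `truth` in the same layout).
#' @param fit optional pre-computed [em_fit] result to reuse.
#' @param ... passed to [em_fit].
#' @return list: `hmm_roc`, `baseline_roc`, `auc` (named vector), `fit`,
#'   `hmm_scores`, `baseline_scores`, `truth` (pooled logical labels).
#' @export
compare_callers <- function(dataset, fit = NULL, ...) {
  stopifnot(!is.null(dataset$count_sets), !is.null(dataset$truth))
  if (is.null(fit)) fit <- em_fit(dataset$count_sets, ...)
  st <- fb_all(dataset$count_sets, fit$params)
  hmm_scores <- st$gamma[, 2]
  base <- independent_bin_test(dataset$count_sets)
  labels <- unlist(dataset$truth, use.names = FALSE) == 2L
  hmm_roc <- roc_auc(hmm_scores, labels)
  baseline_roc <- roc_auc(base$score, labels)
  list(hmm_roc = hmm_roc, baseline_roc = baseline_roc,
       auc = c(hmm = hmm_roc$auc, baseline = baseline_roc$auc),
       fit = fit, hmm_scores = hmm_scores, baseline_scores = base$score,
       truth = labels)
}

#' Matched-sensitivity comparison on worked-example replicates
#'
#' Reproduces the single-gene benchmark: replicate 100-bin genes with 10
#' methylated bins each (see [simulate_worked_example]); one shared HMM is
#' fitted across all replicates, then per replicate both callers are
#' evaluated at the operating point where 8 of the 10 methylated bins are
#' recovered. The HMM is scored by posterior methylation probability, the
#' baseline by its exact-binomial score computed within the replicate gene.
#' Viterbi true-positive counts per replicate are also reported.
#'
#' @param sim output of [simulate_worked_example].
#' @param sensitivity matched sensitivity (default 0.8).
#' @param ... passed to [em_fit].
#' @return data frame with one row per replicate: `hmm_fp`, `baseline_fp`
#'   (false-positive bin counts), `hmm_fpr`, `baseline_fpr` (percent of the
#'   unmethylated bins), `viterbi_tp` (methylated bins decoded as such).
#' @export
worked_example_eval <- function(sim, sensitivity = 0.8, ...) {
  stopifnot(!is.null(sim$count_sets), !is.null(sim$truth))
  fit <- em_fit(sim$count_sets, ...)
  st <- fb_all(sim$count_sets, fit$params)
  gamma2 <- split(st$gamma[, 2], rep(seq_along(st$lens), st$lens))
  paths <- viterbi_all(sim$count_sets, fit$params)
  rows <- lapply(seq_along(sim$count_sets), function(g) {
    truth <- sim$truth[[g]] == 2L
    hmm <- fpr_at_sensitivity(gamma2[[g]], truth, sensitivity)
    base <- independent_bin_test(sim$count_sets[[g]])
    bl <- fpr_at_sensitivity(base$score, truth, sensitivity)
    data.frame(hmm_fp = hmm$n_fp, baseline_fp = bl$n_fp,
               hmm_fpr = 100 * hmm$fpr, baseline_fpr = 100 * bl$fpr,
               viterbi_tp = sum(paths[[g]] == 2L & truth))
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  out
}
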