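GAMMA_CLAMP <- c(1e-10, 1 - 1e-10)

#' Per-bin peak scores: log posterior odds of methylation
#'
#' `score_n = ln( P(z_n = methylated | x) / P(z_n = unmethylated | x) )`,
#' with posteriors clamped to `[1e-10, 1 - 1e-10]` so saturated bins give a
#' finite score of about +/- 23.03.
#'
#' @param gamma N x 2 posterior matrix (rows sum to 1), as produced by
#'   [forward_backward].
#' @return numeric vector of per-bin log-odds scores.
#' @export
bin_peak_scores <- function(gamma) {
  g <- pmin(pmax(gamma, GAMMA_CLAMP[1]), GAMMA_CLAMP[2])
  log(g[, 2] / g[, 1])
}

#' Assemble peak regions from a decoded state path
#'
#' Maximal runs of the methylated state become candidate peak regions; a
#' region's score is the arithmetic mean of its member bins' log-odds
#' scores. Bin indices are 0-based half-open (`[bin_start, bin_end)`). When
#' a [bin_track] is supplied, each region also carries its genomic blocks
#' (member bins' blocks with abutting blocks merged), chromosome and strand.
#'
#' @param path integer state path in `{1, 2}` from [viterbi].
#' @param scores per-bin scores from [bin_peak_scores], same length.
#' @param track optional [bin_track] for genomic projection.
#' @param gene_id gene identifier (defaults to the track's).
#' @return data frame with one row per region: `gene_id`, `bin_start`,
#'   `bin_end`, `n_bins`, `peak_score` and, with a track, `chrom`, `strand`
#'   and a `blocks` list column.
#' @export
call_regions <- function(path, scores, track = NULL, gene_id = NA_character_) {
  stopifnot(length(path) == length(scores), all(path %in% c(1L, 2L)))
  if (!is.null(track)) {
    stopifnot(inherits(track, "bin_track"), track$n_bins == length(path))
    gene_id <- track$gene_id
  }
  r <- rle(path == 2L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  keep <- which(r$values)
  out <- data.frame(gene_id = rep(gene_id, length(keep)),
                    bin_start = starts[keep], bin_end = ends[keep],
                    stringsAsFactors = FALSE)
  out$n_bins <- out$bin_end - out$bin_start
  out$peak_score <- vapply(seq_len(nrow(out)), function(i) {
    mean(scores[(out$bin_start[i] + 1):out$bin_end[i]])
  }, numeric(1))
  if (!is.null(track) && nrow(out) > 0) {
    out$chrom <- track$chrom
    out$strand <- track$strand
    out$blocks <- lapply(seq_len(nrow(out)), function(i) {
      b <- do.call(rbind,
                   track$bin_to_blocks[(out$bin_start[i] + 1):out$bin_end[i]])
      merge_adjacent_blocks(b)
    })
  }
  out
}

# merge genomic blocks that abut (end == next start)
merge_adjacent_blocks <- function(b) {
  if (nrow(b) <= 1) return(b)
  keep_start <- c(TRUE, b[-1, 1] != b[-nrow(b), 2])
  grp <- cumsum(keep_start)
  cbind(start = tapply(b[, 1], grp, min), end = tapply(b[, 2], grp, max))
}

#' Significance testing of peak regions
#'
#' The per-bin log-odds scores, pooled over every bin of every gene, are
#' taken as draws from a Gaussian null with mean `mu` and standard deviation
#' `sigma` (sample sd, n - 1). Each region's mean score is z-transformed
#' against that null, tested one-sided (upper tail), and the p-values are
#' Benjamini-Hochberg adjusted across all tested regions.
#'
#' @param regions region data frame from [call_regions].
#' @param all_bin_scores numeric vector of every bin's score,
#'   transcriptome-wide.
#' @param se_scale `"bin"` (default) compares region scores against the raw
#'   bin-score sd; `"region-mean"` divides sigma by `sqrt(n_bins)`, treating
#'   the region mean as an average of independent bin scores.
#' @return `regions` with columns `z`, `p_value`, `fdr` added.
#' @export
test_significance <- function(regions, all_bin_scores,
                              se_scale = c("bin", "region-mean")) {
  se_scale <- match.arg(se_scale)
  if (length(all_bin_scores) < 2) stop("need at least 2 bin scores")
  mu <- mean(all_bin_scores)
  sigma <- sd(all_bin_scores)
  if (sigma == 0) stop("degenerate score distribution: sd of bin scores is 0")
  if (nrow(regions) == 0) {
    regions$z <- numeric(0); regions$p_value <- numeric(0)
    regions$fdr <- numeric(0)
    return(regions)
  }
  denom <- if (se_scale == "bin") sigma else sigma / sqrt(regions$n_bins)
  regions$z <- (regions$peak_score - mu) / denom
  regions$p_value <- pnorm(regions$z, lower.tail = FALSE)
  regions$fdr <- p.adjust(regions$p_value, method = "BH")
  regions
}

#' Filter peaks at an FDR threshold
#'
#' Keeps regions with `fdr` strictly below the threshold (default 0.025).
#'
#' @param regions region data frame carrying an `fdr` column.
#' @param fdr_threshold cutoff.
#' @return the filtered data frame.
#' @export
filter_peaks <- function(regions, fdr_threshold = 0.025) {
  if (nrow(regions) == 0) return(regions)
  stopifnot(!is.null(regions$fdr))
  regions[regions$fdr < fdr_threshold, , drop = FALSE]
}
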