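#' Call methylation peaks from bin counts
#'
#' End-to-end peak calling on pre-binned counts: fit the HMM by EM (one
#' parameter set shared across genes, or independently per gene), decode
#' each gene by Viterbi, score bins by posterior log-odds, assemble maximal
#' methylated runs into regions, z-test region scores against the pooled
#' bin-score distribution and control FDR by Benjamini-Hochberg.
#'
#' @param count_sets named list of [bin_counts].
#' @param tracks optional named list of [bin_track] aligned with
#'   `count_sets`, enabling genomic block projection of peaks.
#' @param fdr_threshold report peaks with FDR strictly below this (default
#'   0.025); `NULL` keeps all regions.
#' @param sharing `"global"` (one theta for all genes) or `"per-gene"`.
#' @param tol,max_iter EM convergence controls (see [em_fit]).
#' @param se_scale see [test_significance].
#' @param verbose log EM progress and tallies.
#' @return list of class `peak_call`: `peaks` (filtered data frame),
#'   `all_regions` (unfiltered, with significance), `fit` (global mode),
#'   `bin_scores` (per-gene list), `paths` (per-gene Viterbi states).
#' @export
call_peaks <- function(count_sets, tracks = NULL, fdr_threshold = 0.025,
                       sharing = c("global", "per-gene"), tol = 1e-6,
                       max_iter = 100, se_scale = c("bin", "region-mean"),
                       verbose = FALSE) {
  sharing <- match.arg(sharing)
  se_scale <- match.arg(se_scale)
  if (inherits(count_sets, "bin_counts")) count_sets <- list(count_sets)
  stopifnot(length(count_sets) >= 1)
  if (!is.null(tracks)) {
    stopifnot(length(tracks) == length(count_sets))
    for (i in seq_along(tracks)) {
      if (tracks[[i]]$n_bins != length(count_sets[[i]]$x)) {
        stop("track/counts bin mismatch for gene ", tracks[[i]]$gene_id)
      }
    }
  }
  ids <- vapply(count_sets, `[[`, character(1), "gene_id")
  if (sharing == "global") {
    fit <- em_fit(count_sets, tol = tol, max_iter = max_iter, verbose = verbose)
    st <- fb_all(count_sets, fit$params)
    gamma_by_gene <- lapply(split(seq_len(nrow(st$gamma)),
                                  rep(seq_along(st$lens), st$lens)),
                            function(ii) st$gamma[ii, , drop = FALSE])
    paths <- viterbi_all(count_sets, fit$params)
  } else {
    fits <- lapply(count_sets, function(cs) {
      if (all(cs$t == 0)) return(NULL)
      em_fit(cs, tol = tol, max_iter = max_iter)
    })
    gamma_by_gene <- lapply(seq_along(count_sets), function(i) {
      if (is.null(fits[[i]])) {
        matrix(0.5, length(count_sets[[i]]$x), 2)
      } else forward_backward(count_sets[[i]], fits[[i]]$params)$gamma
    })
    paths <- lapply(seq_along(count_sets), function(i) {
      if (is.null(fits[[i]])) rep(1L, length(count_sets[[i]]$x))
      else viterbi(count_sets[[i]], fits[[i]]$params)
    })
    fit <- fits
  }
  bin_scores <- lapply(gamma_by_gene, bin_peak_scores)
  regions <- do.call(rbind, lapply(seq_along(count_sets), function(i) {
    call_regions(paths[[i]], bin_scores[[i]],
                 track = if (is.null(tracks)) NULL else tracks[[i]],
                 gene_id = ids[i])
  }))
  if (is.null(regions)) {
    regions <- call_regions(integer(0), numeric(0), gene_id = NA_character_)
  }
  all_scores <- unlist(bin_scores, use.names = FALSE)
  regions <- test_significance(regions, all_scores, se_scale = se_scale)
  peaks <- if (is.null(fdr_threshold)) regions
           else filter_peaks(regions, fdr_threshold)
  if (verbose) {
    message(sprintf("%d region(s) tested, %d peak(s) kept on %d gene(s)",
                    nrow(regions), nrow(peaks),
                    length(unique(peaks$gene_id))))
  }
  structure(list(peaks = peaks, all_regions = regions, fit = fit,
                 bin_scores = stats::setNames(bin_scores, ids),
                 paths = stats::setNames(paths, ids)),
            class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf("Peak call: %d peak(s) on %d gene(s) (%d region(s) tested)\n",
              nrow(x$peaks), length(unique(x$peaks$gene_id)),
              nrow(x$all_regions)))
  invisible(x)
}

#' Full pipeline from annotation and BAM files
#'
#' Reads the annotation, bins every transcript, counts IP and control reads
#' per bin, calls peaks with [call_peaks] and, when `out_prefix` is given,
#' writes `<prefix>.bed` (BED12), `<prefix>.tsv` (exact scores) and
#' `<prefix>.params.txt` (fitted parameters).
#'
#' @param annotation GTF or BED12 path.
#' @param ip_bam,ctrl_bam indexed BAM files for IP and control.
#' @param bin_size bin width in nt.
#' @param out_prefix optional output prefix.
#' @param ... passed to [call_peaks].
#' @return the [call_peaks] result, invisibly when writing output.
#' @export
run_peak_calling <- function(annotation, ip_bam, ctrl_bam, bin_size = 100,
                             out_prefix = NULL, ...) {
  models <- read_annotation(annotation)
  if (length(models) == 0) stop("annotation contains no usable gene models")
  chroms <- unique(vapply(models, `[[`, character(1), "chrom"))
  for (bam in c(ip_bam, ctrl_bam)) {
    hdr <- names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
    if (!any(chroms %in% hdr)) {
      stop("no chromosome shared between annotation and ", bam)
    }
  }
  tracks <- lapply(models, bin_transcript, bin_size = bin_size)
  count_sets <- lapply(tracks, function(tr) {
    bin_counts(tr$gene_id, count_bam_reads(ip_bam, tr),
               count_bam_reads(ctrl_bam, tr))
  })
  keep <- vapply(count_sets, function(cs) sum(cs$t) > 0, logical(1))
  if (!any(keep)) stop("no informative bins: all combined counts are zero")
  res <- call_peaks(count_sets[keep], tracks = tracks[keep], ...)
  if (!is.null(out_prefix)) {
    write_peaks_bed(res$peaks, paste0(out_prefix, ".bed"))
    write_peaks_tsv(res$peaks, paste0(out_prefix, ".tsv"))
    if (inherits(res$fit, "hmm_fit")) {
      write_hmm_params(res$fit$params, paste0(out_prefix, ".params.txt"))
    }
    return(invisible(res))
  }
  res
}
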