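#' Write per-bin counts as a tab-delimited table
#'
#' The table has columns `gene`, `bin` (1-based index), `ip`, `control`,
#' preceded by `#`-prefixed comment lines (e.g. a seed echo) when `comments`
#' is given. This plain format bypasses alignment I/O entirely.
#'
#' @param count_sets list of [bin_counts].
#' @param path output file.
#' @param comments optional character vector written as `# ` header lines.
#' @export
write_count_table <- function(count_sets, path, comments = NULL) {
  if (inherits(count_sets, "bin_counts")) count_sets <- list(count_sets)
  df <- do.call(rbind, lapply(count_sets, function(cs) {
    data.frame(gene = cs$gene_id, bin = seq_along(cs$x),
               ip = as.integer(cs$x), control = as.integer(cs$y))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  writeLines("gene\tbin\tip\tcontrol", con)
  if (!is.null(df) && nrow(df) > 0) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a per-bin count table
#'
#' @param path tab-delimited file with columns `gene`, `bin`, `ip`,
#'   `control`; `#` lines are ignored.
#' @return named list of [bin_counts], genes in order of first appearance.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene", "bin", "ip", "control")
  if (!all(need %in% names(df))) {
    stop("count table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) return(list())
  genes <- unique(df$gene)
  out <- lapply(genes, function(g) {
    sub <- df[df$gene == g, ]
    sub <- sub[order(sub$bin), ]
    if (!identical(as.integer(sub$bin), seq_len(nrow(sub)))) {
      stop("bins of gene '", g, "' are not a contiguous 1..N sequence")
    }
    bin_counts(g, sub$ip, sub$control)
  })
  names(out) <- genes
  out
}

#' Write called peaks as BED12
#'
#' One line per peak; the block fields encode junction-spanning structure.
#' The BED score column carries the peak score scaled as
#' `min(1000, round(100 * peak_score))`, floored at 0. Exact scores,
#' p-values and FDR belong in the companion table from [write_peaks_tsv].
#'
#' @param peaks peak data frame from [call_peaks]/[test_significance],
#'   with a `blocks` list column of genomic block matrices.
#' @param path output BED file.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (nrow(peaks) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (is.null(peaks$blocks)) stop("peaks carry no genomic blocks")
  lines <- vapply(seq_len(nrow(peaks)), function(i) {
    b <- peaks$blocks[[i]]
    if (is.null(b) || nrow(b) == 0) {
      stop("peak ", i, " (", peaks$gene_id[i], ") has no blocks")
    }
    cs <- b[1, 1]
    ce <- b[nrow(b), 2]
    score <- max(0, min(1000, round(100 * peaks$peak_score[i])))
    paste(peaks$chrom[i], format(cs, scientific = FALSE),
          format(ce, scientific = FALSE), peaks$gene_id[i], score,
          peaks$strand[i], format(cs, scientific = FALSE),
          format(ce, scientific = FALSE), "0", nrow(b),
          paste0(paste(format(b[, 2] - b[, 1], scientific = FALSE, trim = TRUE),
                       collapse = ","), ","),
          paste0(paste(format(b[, 1] - cs, scientific = FALSE, trim = TRUE),
                       collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write the peak table with exact scores and significance
#'
#' @param peaks peak data frame.
#' @param path output TSV.
#' @export
write_peaks_tsv <- function(peaks, path) {
  cols <- c("gene_id", "chrom", "start", "end", "strand", "n_bins",
            "peak_score", "p_value", "fdr")
  df <- peaks
  if (!is.null(df$blocks) && nrow(df) > 0) {
    df$start <- vapply(df$blocks, function(b) b[1, 1], numeric(1))
    df$end <- vapply(df$blocks, function(b) b[nrow(b), 2], numeric(1))
  } else {
    # counts-only runs carry no genomic projection
    df$start <- rep(NA_real_, nrow(df))
    df$end <- rep(NA_real_, nrow(df))
  }
  for (cc in cols) if (is.null(df[[cc]])) df[[cc]] <- rep(NA, nrow(df))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
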