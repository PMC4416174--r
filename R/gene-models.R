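#' Construct a gene model
#'
#' A gene model is the exon structure peaks are projected through: an ordered
#' set of disjoint genomic exon intervals on one chromosome. All coordinates
#' are internal 0-based half-open; GTF input is converted at parse time.
#'
#' @param gene_id record identifier (transcript or gene id).
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix of 0-based half-open `[start, end)` exon
#'   intervals, ascending and non-overlapping.
#' @return an object of class `gene_model` with the derived
#'   `transcript_length` (sum of exon lengths).
#' @export
gene_model <- function(gene_id, chrom, strand, exons) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  stopifnot(nrow(exons) >= 1, all(exons[, 2] > exons[, 1]),
            strand %in% c("+", "-"))
  if (nrow(exons) > 1) {
    exons <- exons[order(exons[, 1]), , drop = FALSE]
    if (any(exons[-1, 1] < exons[-nrow(exons), 2])) {
      stop("exons of '", gene_id, "' overlap")
    }
  }
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand, exons = exons,
                 transcript_length = sum(exons[, 2] - exons[, 1])),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("Gene model %s: %s:%s, %d exon(s), transcript length %d nt\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              as.integer(x$transcript_length)))
  invisible(x)
}

#' Read gene annotation from GTF or BED12
#'
#' GTF records (Ensembl dialect) are grouped into one model per
#' `transcript_id` from their `exon` features; BED12 lines become one model
#' each from their block structure. Overlapping records are kept as
#' independent models: peak calling on concatenated exons sidesteps isoform
#' assignment rather than resolving it.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed12"`.
#' @return named list of [gene_model] objects.
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  }
  first <- readLines(path, n = 100L, warn = FALSE)
  if (!any(nzchar(first) & !grepl("^#", first))) {
    warning("no exon records in ", path)
    return(list())
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[!is.na(gr$type) & gr$type == "exon"]
    if (length(gr) == 0) {
      warning("no exon features in ", path)
      return(list())
    }
    ids <- as.character(gr$transcript_id)
    models <- lapply(split(seq_along(gr), ids), function(ii) {
      sub <- gr[ii]
      gene_model(gene_id = as.character(sub$transcript_id[1]),
                 chrom = as.character(GenomicRanges::seqnames(sub)[1]),
                 strand = as.character(BiocGenerics::strand(sub)[1]),
                 # GTF is 1-based closed; internal is 0-based half-open
                 exons = cbind(BiocGenerics::start(sub) - 1L,
                               BiocGenerics::end(sub)))
    })
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0) {
      warning("no records in ", path)
      return(list())
    }
    blk <- rtracklayer::blocks(gr)
    nm <- if (!is.null(gr$name)) as.character(gr$name)
          else sprintf("record_%d", seq_along(gr))
    models <- lapply(seq_along(gr), function(i) {
      b <- blk[[i]]
      gene_model(gene_id = nm[i],
                 chrom = as.character(GenomicRanges::seqnames(gr)[i]),
                 strand = {
                   s <- as.character(BiocGenerics::strand(gr)[i])
                   if (s %in% c("+", "-")) s else "+"
                 },
                 exons = cbind(BiocGenerics::start(b) - 1L,
                               BiocGenerics::end(b)))
    })
    names(models) <- make.unique(nm)
  }
  models
}

#' Divide a transcript into fixed-width bins
#'
#' Concatenated exons are tiled with `N = ceiling(length / bin_size)`
#' contiguous bins: bins 1..N-1 have exactly `bin_size` nt and the last bin
#' holds the remainder (kept even when short, so 3' signal is not lost).
#' Each bin is mapped back to the genomic intervals it covers; a bin spanning
#' an exon junction maps to two or more blocks.
#'
#' @param gene a [gene_model].
#' @param bin_size bin width in nucleotides (the read length, typically 100).
#' @return an object of class `bin_track`: `gene_id`, `chrom`, `strand`,
#'   `bin_size`, `n_bins`, `bin_to_blocks` (list of block matrices) and the
#'   gene's exon table for coordinate projection.
#' @export
bin_transcript <- function(gene, bin_size) {
  stopifnot(inherits(gene, "gene_model"), bin_size >= 1)
  len <- gene$transcript_length
  n_bins <- as.integer(ceiling(len / bin_size))
  starts <- (seq_len(n_bins) - 1) * bin_size
  ends <- pmin(starts + bin_size, len)
  blocks <- lapply(seq_len(n_bins), function(i) {
    transcript_to_genomic(gene, starts[i], ends[i])
  })
  structure(list(gene_id = gene$gene_id, chrom = gene$chrom,
                 strand = gene$strand, bin_size = bin_size, n_bins = n_bins,
                 bin_to_blocks = blocks, exons = gene$exons,
                 transcript_length = len),
            class = "bin_track")
}

#' Project a transcript interval onto genomic blocks
#'
#' Maps the 0-based half-open transcript interval `[tstart, tend)` through a
#' gene's exon model to the genomic intervals it covers.
#'
#' @param gene a [gene_model].
#' @param tstart,tend transcript coordinates, `0 <= tstart < tend <= length`.
#' @return two-column matrix of 0-based half-open genomic intervals.
#' @export
transcript_to_genomic <- function(gene, tstart, tend) {
  stopifnot(tstart >= 0, tend > tstart, tend <= gene$transcript_length)
  ex <- gene$exons
  w <- ex[, 2] - ex[, 1]
  offs <- cumsum(c(0, w))[seq_len(nrow(ex))]  # transcript offset of each exon
  out <- list()
  for (i in seq_len(nrow(ex))) {
    lo <- max(tstart, offs[i])
    hi <- min(tend, offs[i] + w[i])
    if (hi > lo) {
      out[[length(out) + 1]] <- c(ex[i, 1] + (lo - offs[i]),
                                  ex[i, 1] + (hi - offs[i]))
    }
  }
  matrix(unlist(out), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("start", "end")))
}

#' Project genomic positions onto transcript coordinates
#'
#' @param gene a [gene_model].
#' @param gpos 0-based genomic positions.
#' @return 0-based transcript coordinates; `NA` for positions outside exons.
#' @export
genomic_to_transcript <- function(gene, gpos) {
  ex <- gene$exons
  w <- ex[, 2] - ex[, 1]
  offs <- cumsum(c(0, w))[seq_len(nrow(ex))]
  res <- rep(NA_real_, length(gpos))
  for (i in seq_len(nrow(ex))) {
    hit <- !is.na(gpos) & gpos >= ex[i, 1] & gpos < ex[i, 2]
    res[hit] <- offs[i] + (gpos[hit] - ex[i, 1])
  }
  res
}

#' Per-gene bin counts for the IP and control samples
#'
#' @param gene_id gene identifier.
#' @param x integer vector of IP read counts per bin.
#' @param y integer vector of control read counts per bin, same length.
#' @return an object of class `bin_counts` with the derived total `t = x + y`.
#' @export
bin_counts <- function(gene_id, x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y), length(x) >= 1,
            all(x >= 0), all(y >= 0), all(x == floor(x)), all(y == floor(y)))
  structure(list(gene_id = as.character(gene_id), x = x, y = y, t = x + y),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf("Bin counts for %s: %d bins, %d IP / %d control reads\n",
              x$gene_id, length(x$x), as.integer(sum(x$x)),
              as.integer(sum(x$y))))
  invisible(x)
}
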