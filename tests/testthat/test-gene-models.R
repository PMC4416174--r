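test_that("BED12 records become gene models with 0-based half-open exons", {
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed12_line(f, "chr1", 100, 400, "tx1", "+",
                   block_sizes = c(100, 100), block_starts = c(0, 200))
  models <- read_annotation(f, format = "bed12")
  expect_length(models, 1)
  g <- models[["tx1"]]
  expect_equal(g$exons, cbind(c(100, 300), c(200, 400)), ignore_attr = TRUE)
  expect_equal(g$transcript_length, 200)
  expect_equal(g$strand, "+")
})

test_that("GTF 1-based closed exons are converted at parse time", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr2", "test", "exon", 101, 200, ".", "-", ".",
          'gene_id "g1"; transcript_id "tx1";', sep = "\t"),
    paste("chr2", "test", "exon", 301, 350, ".", "-", ".",
          'gene_id "g1"; transcript_id "tx1";', sep = "\t"),
    paste("chr2", "test", "CDS", 120, 180, ".", "-", ".",
          'gene_id "g1"; transcript_id "tx1";', sep = "\t")), f)
  models <- read_annotation(f, format = "gtf")
  expect_length(models, 1)
  expect_equal(models[["tx1"]]$exons, cbind(c(100, 300), c(200, 350)),
               ignore_attr = TRUE)
  expect_equal(models[["tx1"]]$transcript_length, 150)
  expect_equal(models[["tx1"]]$strand, "-")
})

test_that("an annotation with no exon features yields an empty set with a warning", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(0), f)
  expect_warning(models <- read_annotation(f, format = "gtf"), "no exon")
  expect_length(models, 0)
})

test_that("overlapping or unsorted exon input is caught", {
  expect_error(gene_model("g", "chr1", "+", rbind(c(0, 100), c(50, 150))),
               "overlap")
  g <- gene_model("g", "chr1", "+", rbind(c(300, 400), c(100, 200)))
  expect_equal(g$exons[, 1], c(100, 300), ignore_attr = TRUE)  # sorted on input
})

test_that("bins tile the transcript with a short final remainder bin", {
  g <- gene_model("g", "chr1", "+", rbind(c(100, 200), c(300, 400)))
  tr <- bin_transcript(g, 100)
  expect_equal(tr$n_bins, 2L)
  expect_equal(tr$bin_to_blocks[[1]], cbind(100, 200), ignore_attr = TRUE)
  expect_equal(tr$bin_to_blocks[[2]], cbind(300, 400), ignore_attr = TRUE)

  g2 <- gene_model("g2", "chr1", "+", cbind(0, 250))
  tr2 <- bin_transcript(g2, 100)
  expect_equal(tr2$n_bins, 3L)
  lens <- vapply(tr2$bin_to_blocks, function(b) sum(b[, 2] - b[, 1]), numeric(1))
  expect_equal(lens, c(100, 100, 50))
})

test_that("a junction-spanning bin maps to blocks in both exons", {
  g <- gene_model("g", "chr1", "+", rbind(c(0, 150), c(250, 350)))
  tr <- bin_transcript(g, 100)
  # bin 2 covers transcript [100, 200): 50 nt at the end of exon 1 and
  # 50 nt at the start of exon 2
  expect_equal(tr$bin_to_blocks[[2]], rbind(c(100, 150), c(250, 300)),
               ignore_attr = TRUE)
})

test_that("bin blocks conserve exonic bases exactly for random gene models", {
  set.seed(31)
  for (rep in 1:30) {
    n_ex <- sample(1:5, 1)
    gaps <- sample(50:500, n_ex, replace = TRUE)
    widths <- sample(30:400, n_ex, replace = TRUE)
    ends <- cumsum(gaps + widths)
    g <- gene_model("g", "chrX", sample(c("+", "-"), 1),
                    cbind(ends - widths, ends))
    L <- sample(c(25, 50, 100, 137), 1)
    tr <- bin_transcript(g, L)
    all_blocks <- do.call(rbind, tr$bin_to_blocks)
    merged <- all_blocks[order(all_blocks[, 1]), , drop = FALSE]
    # concatenated bin blocks must reproduce the exon set exactly
    recon <- meripHMM:::merge_adjacent_blocks(merged)
    expect_equal(recon, g$exons, ignore_attr = TRUE)
    # and tile the transcript contiguously without overlap
    expect_equal(sum(all_blocks[, 2] - all_blocks[, 1]), g$transcript_length)
    expect_equal(tr$n_bins, as.integer(ceiling(g$transcript_length / L)))
  }
})

test_that("transcript and genomic projections are mutually inverse", {
  g <- gene_model("g", "chr1", "+", rbind(c(10, 60), c(100, 130), c(200, 220)))
  len <- g$transcript_length
  tpos <- 0:(len - 1)
  gpos <- unlist(lapply(tpos, function(tp) {
    b <- transcript_to_genomic(g, tp, tp + 1)
    b[1, 1]
  }))
  expect_equal(genomic_to_transcript(g, gpos), as.numeric(tpos))
  expect_true(all(is.na(genomic_to_transcript(g, c(0, 75, 150, 500)))))
})
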