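# Build tiny alignment and annotation fixtures in code (text SAM converted
# to BAM on the fly; nothing binary is stored in the repository).

# reads: data.frame(qname, flag, chrom, pos (1-based), cigar)
make_test_bam <- function(reads, chrom_lengths, dir = NULL) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sam <- file.path(dir, "reads.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  reads <- reads[order(match(reads$chrom, names(chrom_lengths)), reads$pos), ]
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag, reads$chrom, reads$pos,
                  reads$cigar,
                  strrep("A", 10), strrep("I", 10))
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

write_bed12_line <- function(path, chrom, start, end, name, strand,
                             block_sizes, block_starts) {
  writeLines(paste(chrom, start, end, name, 0, strand, start, end, "0",
                   length(block_sizes),
                   paste0(paste(block_sizes, collapse = ","), ","),
                   paste0(paste(block_starts, collapse = ","), ","),
                   sep = "\t"), path)
  path
}
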