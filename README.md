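# meripHMM

HMM-based peak calling for MeRIP-seq (m6A) data on exome-projected
transcript bins.

MeRIP-seq pairs an antibody-enriched IP library with an expression control
to locate RNA methylation sites transcriptome-wide. Peak callers that test
each genomic window independently miss weakly enriched bins inside real
peaks and promote isolated noisy bins to spurious ones. `meripHMM` models
the methylation state of *consecutive* bins explicitly, for anyone calling
m6A (or comparable RNA-modification) peaks from IP/control count data:
bioinformaticians working from aligned BAMs, and methodologists who want a
transparent, testable reference implementation with a matching simulator
and baseline.

## The model

Each gene's exons are concatenated and tiled with bins of one read length
(default 100 nt). With `x_n` the IP count, `y_n` the control count and
`t_n = x_n + y_n` in bin `n`, the hidden state `z_n ∈ {1 = unmethylated,
2 = methylated}` follows a two-state Markov chain with transition matrix
`A` and initial probability `π = P(z_1 = 1)`, and the two samples collapse
into one binomial emission:

    x_n | z_n, t_n ~ Binomial(t_n, p_{z_n}),      p_1 < p_2,

where `p_k` is the IP fraction of the combined counts expected in state
`k`. The parameters `θ = {π, A, p_1, p_2}` are fitted by multi-sequence EM
(forward–backward E step, closed-form M step, one `θ` shared across
genes); Viterbi decoding yields peak regions as maximal methylated runs;
each region is scored by the mean per-bin posterior log-odds
`ln γ(z_n,2)/γ(z_n,1)`, z-tested against the pooled bin-score
distribution, and reported at Benjamini–Hochberg FDR < 0.025. Peaks are
projected back to genomic blocks and written as BED12 plus a TSV with
exact scores. See the vignette (`vignettes/hmm-peak-calling.Rmd`) for
assumptions, numerical choices and limitations.

## Worked example

Simulate a sparsely methylated transcriptome (1000 genes, ~7% of bins
methylated), fit the HMM and call peaks:

```r
library(meripHMM)

cfg <- sim_config(n_genes = 1000, pi = 0.95,
                  A = matrix(c(0.97, 0.03, 0.4, 0.6), 2, byrow = TRUE))
ds  <- simulate_merip(cfg, seed = 20)
res <- call_peaks(ds$count_sets)
res
#> Peak call: 481 peak(s) on 399 gene(s) (654 region(s) tested)
res$fit$params
#> Two-state binomial-emission HMM parameters
#>   pi (P(z1 = unmethylated)): 0.9336
#>   A: [0.9583 0.0417; 0.4826 0.5174]
#>   p: (0.3298, 0.8168)
head(res$peaks[order(res$peaks$fdr), c("gene_id", "bin_start", "bin_end",
                                       "peak_score", "p_value", "fdr")], 3)
#>               gene_id bin_start bin_end peak_score      p_value         fdr
#> gene_00009 gene_00009         9      10   23.02585 0.0003797354 0.001043474
#> gene_00010 gene_00010         6       7   23.02585 0.0003797354 0.001043474
#> gene_00022 gene_00022         0       1   23.02585 0.0003797354 0.001043474
```

The fit recovers the generating chain (`π` 0.93 vs 0.95 true, sticky
background row, IP fractions 0.33/0.82), and the top peaks are saturated
posterior calls (log-odds clamp at 23.03) with small BH-adjusted FDR.
`bin_start`/`bin_end` are 0-based half-open bin indices on the transcript;
with an annotation the peaks also carry genomic blocks and can be written
with `write_peaks_bed()` / `write_peaks_tsv()`.

On the dense validation configuration (5000 genes, 75% methylated bins,
the package's standard validation settings), the HMM's posterior scores
separate methylated from unmethylated bins better than an independent-bin
exact binomial test on the identical counts:

```r
cmp <- compare_callers(simulate_merip(sim_config(), seed = 20))
round(cmp$auc, 4)
#>      hmm baseline
#>   0.9765   0.9686
```

Starting from BAM files instead:

```r
res <- run_peak_calling("genes.gtf", "ip.bam", "ctrl.bam",
                        bin_size = 100, out_prefix = "peaks")
```

or from the shell via the bundled CLI
(`inst/cli/merip-hmm call|simulate|eval`).

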