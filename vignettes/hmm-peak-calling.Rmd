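---
title: "HMM-based peak calling for MeRIP-seq: model, assumptions and design"
author: "meripHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HMM-based peak calling for MeRIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meripHMM)
```

## The problem

MeRIP-seq measures transcriptome-wide RNA methylation (chiefly m6A) with a
pair of samples: an IP library enriched for methylated fragments by an
anti-m6A antibody, and a control library measuring plain expression. Reads
pile up around methylation sites in the IP sample, so site discovery is a
peak-calling problem — but unlike ChIP-seq peaks, m6A peaks live on
transcripts and may span exon–exon junctions, and the control coverage
varies with expression. `meripHMM` therefore works on *exome-projected*
coordinates: each gene's exons are concatenated into a transcript, tiled
with bins of roughly one read length (100 nt by default), and peak calling
happens on those bins. Called peaks are projected back to genomic blocks
and written as BED12, so junction-spanning peaks stay intact. Working per
gene on concatenated exons also sidesteps isoform assignment: each
annotation record is processed independently.

## The model

For gene with $N$ bins, let $x_n$ be the IP read count in bin $n$, $y_n$
the control count, and $t_n = x_n + y_n$. The hidden methylation state
$z_n \in \{1, 2\}$ (1 = unmethylated, 2 = methylated) follows a first-order
Markov chain:

$$A_{jk} = P(z_n = k \mid z_{n-1} = j), \qquad P(z_1 = 1) = \pi.$$

Modelling $x_n$ and $y_n$ as Poisson with rates that depend on $z_n$ in the
IP but not the control, and conditioning on the total $t_n$, collapses both
samples into a single binomial emission:

$$x_n \mid z_n, t_n \sim \mathrm{Binomial}(t_n,\, p_{z_n}),$$

where $p_k$ is the expected IP fraction of the combined count in state
$k$. The Poisson rates and sequencing depths never need to be inferred
separately; they are absorbed into $p_1 < p_2$. This ordering is the
identifiability convention: the methylated state is by definition the
IP-enriched one, and the M step relabels states whenever an update violates
it.

The chain captures what an independent-bin test cannot: a bin with
unremarkable enrichment sitting between two strongly enriched bins is
probably part of the same peak, and a single noisy outlier bin probably is
not.

### Fitting

Parameters $\theta = \{\pi, A, p_1, p_2\}$ are estimated by
expectation–maximization. The E step runs the scaled forward–backward
recursions, giving marginal posteriors $\gamma(z_n, k)$, pairwise
posteriors $\varepsilon(z_{n-1}, j, z_n, k)$ and the data log-likelihood
from the scaling constants (binomial coefficients included, so the
monotonicity guarantee is testable on the reported trace). The M step has
closed forms: $\pi$ from the first-bin posteriors, $A$ from row-normalized
pooled $\varepsilon$ sums, and

$$p_k = \frac{\sum_n \gamma(z_n,k)\, x_n}{\sum_n \gamma(z_n,k)\, t_n},$$

all pooled across genes. By default one $\theta$ is shared by the whole
transcriptome (multi-sequence EM, each gene an independent chain restarting
from $\pi$): per-gene chains of 5–30 bins are too short to estimate four
free parameters stably, and a shared parameter set matches how the method
is applied in practice. `sharing = "per-gene"` is available when genes are
long and heterogeneous.

After convergence, the Viterbi algorithm decodes the MAP state path per
gene; maximal runs of the methylated state become candidate peak regions.

### Scoring and significance

Each bin gets the posterior log-odds score
$\mathrm{score}_n = \ln\{\gamma(z_n,2)/\gamma(z_n,1)\}$, and a region's
score is the mean over its member bins. Region scores are z-transformed
against the mean and standard deviation of *all* bin scores pooled
transcriptome-wide, tested one-sided (upper tail), and Benjamini–Hochberg
adjusted; peaks are reported at FDR < 0.025 by default (strict
inequality).

This pooled Gaussian reference presumes that most of the transcriptome is
background, so that the pooled mean sits near the unmethylated mode. When
the methylated fraction is large — as in the validation simulator's
default regime, where the chain's stationary distribution is 75%
methylated — every region's score sits close to the pooled mean, the
z-ceiling is roughly $\sqrt{(1-f)/f}$ for methylated fraction $f$, and
essentially nothing can reach a small FDR. That is a property of the
scoring definition, not a bug: significance testing is informative in the
sparse-methylation regime of real data, while the dense simulation regime
is evaluated by ROC on raw scores and by Viterbi decoding. The test suite
exercises FDR-based recovery under a sparse configuration
($\pi = 0.95$, $A = [[0.97, 0.03], [0.4, 0.6]]$, about 7% methylated) and
ROC/decoding under the dense validation configuration.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `bin_size` | 100 nt | bin width on the concatenated exons; chosen as the typical fragment/read length so one fragment informs about one bin |
| `fdr_threshold` | 0.025 | BH-adjusted cutoff for reported peaks (strict `<`) |
| `tol` | 1e-6 | relative log-likelihood change that stops EM |
| `max_iter` | 100 | EM iteration cap |
| `sharing` | global | one $\theta$ for all genes vs per-gene fits |
| `se_scale` | bin | z-denominator: raw bin-score sd (literal reading of the scoring rule) or sd$/\sqrt{n_\text{bins}}$ for the region mean (`"region-mean"`) |

EM initialization (data-driven, ordering-safe): $\pi = 0.5$,
$A = [[0.8, 0.2], [0.2, 0.8]]$, and $p_1, p_2$ at the 25th/75th
percentiles of the observed per-bin IP fraction $x_n/t_n$ over non-empty
bins, pushed apart to at least 0.1 if the quartiles nearly coincide.

## Numerical choices

- **Scaled, not log-space, forward–backward.** Per-position normalization
  gives the exact pairwise posteriors directly and the log-likelihood as
  the sum of log scaling constants. Emissions are additionally rescaled by
  their per-bin maximum before exponentiation, so even extreme counts
  cannot underflow both states simultaneously.
- **Empty bins stay in the chain.** A bin with $t_n = 0$ has emission
  probability 1 in both states; it carries no emission information but
  preserves transition structure, letting a peak bridge a coverage gap.
- **Clamps.** $p_k$ is clamped to $[10^{-6}, 1 - 10^{-6}]$ before logs;
  posteriors are clamped to $[10^{-10}, 1 - 10^{-10}]$ inside the log-odds
  score, so saturated bins score $\pm\ln 10^{10} \approx \pm 23.03$.
- **Viterbi ties break toward the unmethylated state** at every
  comparison, making peak calling conservative under exact ties.
- **Degenerate M-step denominators** (a state with no posterior mass, or
  no outgoing transitions) keep the previous parameter value with a
  warning rather than producing NaN.
- **Sample standard deviation** (n − 1) is used in the z-transform; at
  transcriptome scale the choice is numerically irrelevant but it is fixed
  for determinism.
- Convergence is declared when $|\Delta \ell| / |\ell| <$ `tol`; the trace
  of $\ell$ is recorded per iteration and asserted non-decreasing (slack
  $10^{-8}$) throughout the test suite.

## Read counting

Alignment belongs to external tools; this package
consumes coordinate-sorted, indexed BAM (or a plain per-bin count table,
bypassing alignment I/O entirely). Assigning a read to a single bin is a
genuinely open design choice; the package uses the **transcript
midpoint rule**: an alignment's reference blocks are intersected with the
exon model, the first and last exonic aligned bases are projected to
transcript coordinates, and the midpoint of that span picks the bin. The
rule is symmetric and robust to junction-spanning reads (intron length
cannot shift the midpoint). Secondary and supplementary alignments are
excluded; duplicates are kept: standard MeRIP-seq preprocessing removes
multi-mapping reads and nothing more. Reads aligned wholly outside the
exon model are ignored.

## The simulator

`simulate_merip()` defines the package's standing validation study: 5000 genes with lengths
uniform on 500–3000 nt, states from the chain
$A = [[0.7, 0.3], [0.1, 0.9]]$, $\pi = 0.2$; per gene a control rate
$\lambda_{\mathrm{ctrl}} \sim U(5, 20)$ held constant across bins; per bin
an IP rate $\lambda_{\mathrm{IP}} \sim U(\lambda_{\mathrm{ctrl}}, 100)$
when methylated and $U(0, \lambda_{\mathrm{ctrl}})$ when unmethylated;
counts Poisson at equal (unit) depths. Two generative choices fixed here once: the simulation bin size is 100 nt (the stated fragment length),
and $\lambda_{\mathrm{IP}}$ is redrawn per bin rather than per region,
giving the within-peak count heterogeneity visible in real coverage.

Two things the simulator deliberately does *not* emulate: read-level
artifacts (fragment-length, GC and mappability effects — counts are drawn
directly, not reads), and the binomial emission itself. Because
$\lambda_{\mathrm{IP}}$ varies per bin, the per-bin IP fraction is a
random variable, so the fitted $p_1, p_2$ are effective averages and the
emission is overdispersed relative to a single binomial. This
misspecification is intentional — it is the validation regime this family of callers is
conventionally judged under — but it means two test-design consequences:
parameter-recovery tests use `simulate_hmm_counts()`, a direct
binomial-emission generator where true $p_k$ exist; and the exact-binomial
baseline's p-values are only guaranteed super-uniform under that matched
generator, not under the Poisson regime.

`simulate_worked_example()` generates replicate single genes of 100 bins
with one contiguous block of 10 methylated bins at a uniformly random
position — a single-gene benchmark where the advantage of modelling bin
dependence is most visible.

## The independent-bin baseline

The comparison baseline treats every bin independently: pooled null IP
fraction $p_0 = \sum x_n / \sum t_n$, per-bin one-sided exact binomial
tail $P(X \ge x_n \mid t_n, p_0)$, score $-\ln p$. This is a surrogate for
the bin-independent callers used in this field, not a re-implementation of
any particular one (production tools add window smoothing and library-size
normalization of their own). It is a strong discriminator in its own
right: on the worked-example replicates its false-positive counts at
matched sensitivity are low, and comparisons against it measure the value
of modelling bin dependence, nothing else.

## Validation problem sizes

The shipped checks run the full 5000-gene configuration (about 90,000
bins) for headline ROC/AUC values averaged over three seeds; a 20-seed
HMM-vs-baseline superiority sweep at 400 genes per seed; 200–300
worked-example replicates for matched-sensitivity operating points;
exhaustive-enumeration cross-checks for every chain length up to 10; and
parameter recovery on roughly $1.2 \times 10^5$ bins. These sizes were
chosen so each quantity's sampling error is comfortably below the
tolerance it is compared at.

## Known limitations

- Two states only; partial-methylation or multi-level enrichment collapses
  into the methylated state.
- One IP/control pair; replicates must be pooled upstream, and
  differential methylation between conditions is out of scope.
- The binomial emission ignores overdispersion beyond what the shared
  $p_k$ absorbs; strongly expression-dependent enrichment biases are not
  modelled.
- Region significance presumes sparse methylation (see above); in
  dense-signal data the ranking by score remains valid but pooled
  z-p-values compress toward 0.5.
- Peak summits are not estimated; resolution is the bin size.
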