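Package: meripHMM
Title: HMM-Based Exome Peak Calling for MeRIP-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects N6-methyladenosine (m6A) peaks from MeRIP-seq IP/control
    read counts with a two-state hidden Markov model on concatenated-exon
    (transcript) bins. Emissions are binomial on the IP fraction of combined
    counts, parameters are fitted by multi-sequence EM, peaks are decoded by
    Viterbi and scored by the mean posterior log-odds of the methylated state,
    with a Gaussian z-test and Benjamini-Hochberg FDR control. Includes a
    Poisson read-count simulator for validation studies, an independent-bin
    exact binomial baseline, ROC/AUC comparison machinery, and BED12/TSV
    output of junction-spanning peak regions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    GenomicAlignments,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
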