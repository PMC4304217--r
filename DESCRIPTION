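Package: lfcseq
Title: Nonparametric Differential Expression Analysis of RNA-seq Counts via
    Local Empirical Null Distributions of Log Fold Changes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements LFCseq, a nonparametric test for differential gene
    expression between two conditions from an RNA-seq count matrix. The test
    statistic is the log2 fold change of mean normalized counts; its null
    distribution is estimated per gene by pooling within-condition log fold
    changes over half-splits of each condition's samples, restricted to a
    neighborhood of genes with similar expression strength. Includes
    goodness-of-fit sequencing-depth normalization, a common-null (L, D)
    baseline and a per-gene permutation baseline, a negative binomial count
    simulator with ground truth, ROC/AUC, FDR-curve and
    precision/sensitivity/F-score evaluation, and a benchmark driver for
    repeated simulate-test-evaluate experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
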