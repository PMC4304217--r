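# lfcseq

Nonparametric differential expression analysis of RNA-seq count data using
gene-specific empirical null distributions of log fold changes.

## What it does and for whom

Given a genes × samples matrix of read counts and a two-condition design,
`lfcseq` tests each gene for differential expression (DE) without assuming a
count distribution. It is aimed at the small-replicate regime (2–8 samples
per condition) where parametric negative binomial tests depend on fragile
dispersion estimates.

The test statistic is the log fold change of mean normalized counts,

    L_i = log2( n̄_iA / n̄_iB ),

and its null distribution is estimated from the data: each condition's
samples are split into two halves in every possible way (or 20 random ways
for more than 7 samples), the half-vs-half log fold changes — pure
within-condition noise — are pooled, and gene *i* draws its null only from
the *k* = 50 genes whose overall expression is closest to its own. The
probability of gene *i* being non-DE is the fraction of this gene-specific
null exceeding the observed statistic in magnitude,

    P(x_i = 0) = #{ l in L_i : |l| > |L_i| } / |L_i|,

and genes with P < 0.1 are called DE. Pooling by expression neighborhood
matters because the noise level of log fold changes falls sharply with
expression strength; a null pooled over all genes is too wide for strongly
expressed genes and too narrow for weakly expressed ones.

The package also ships the surrounding benchmark machinery: goodness-of-fit
sequencing-depth normalization, a common-null (L, D) baseline and a per-gene
permutation baseline, a seeded negative binomial simulator with ground
truth, AUC / FDR-curve / precision–sensitivity–F-score evaluation, and a
repeated simulate–test–evaluate benchmark driver.

## Worked example

```r
library(lfcseq)

# a 5000-gene NB dataset: 30% DE genes, 5 samples per condition
p   <- sim_params(n_genes = 5000, n_A = 5, n_B = 5, seed = 42)
sim <- simulate_sim1(p)

res <- run_lfcseq(sim$counts, sim$design)
head(res[order(res$prob_nonDE), ], 5)
#>  gene_id mean_A mean_B log2FC prob_nonDE de_call
#>    g0261 4851.0  23348 -2.267          0       1
#>    g0548  711.2   3898 -2.454          0       1
#>    g2031 1131.4  10340 -3.192          0       1
#>    g2477 1780.2  14549 -3.031          0       1
#>    g2590 1317.3   8635 -2.713          0       1
sum(res$de_call)
#> [1] 1028

kept <- rowSums(sim$counts) > 0
ev <- evaluate_results(1 - res$prob_nonDE, res$de_call, sim$truth[kept])
sprintf("AUC %.3f  PRE %.3f  SEN %.3f  FS %.3f", ev$auc, ev$pre, ev$sen, ev$fs)
#> [1] "AUC 0.921  PRE 0.920  SEN 0.631  FS 0.748"
```

The top-ranked genes all have null probability exactly 0 — none of the
~1000 within-condition log fold changes in their neighborhoods reaches
their observed 2–3 log2-unit shifts. Of the 5000 genes, 1028 are called at
the 0.1 cutoff; against the simulated truth that is 92% precision at 63%
sensitivity, and the probability ranking separates DE from non-DE genes
with AUC 0.92.

A thin command-line wrapper over the same functions is installed at
`inst/cli/lfcseq.R`:

    Rscript inst/cli/lfcseq.R simulate --n-genes 2000 --n-a 5 --n-b 5 --seed 1 --out-prefix sim
    Rscript inst/cli/lfcseq.R test --counts sim_counts.tsv --design sim_design.tsv --out res.tsv
    Rscript inst/cli/lfcseq.R evaluate --results res.tsv --truth sim_truth.tsv --out eval.json

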