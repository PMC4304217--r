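---
title: "Gene-specific empirical nulls for RNA-seq differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-specific empirical nulls for RNA-seq differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lfcseq)
```

## The problem

In a two-condition RNA-seq experiment we observe a matrix of read counts
$N_{ij}$ for gene $i$ in sample $j$, with each sample belonging to condition
$A$ or $B$, and want to decide for each gene whether it is differentially
expressed (DE). Parametric tests (negative binomial GLMs and their
relatives) are powerful when their distributional assumptions hold, but with
the 2–8 replicates typical of such designs, dispersion estimation is fragile
and miscalibration is common. `lfcseq` implements a nonparametric
alternative: the test statistic is simply the log fold change of mean
normalized counts, and its null distribution is *estimated from the data
itself*, separately for every gene, using only genes of similar expression
strength.

## The statistic and its empirical null

After normalization (below), let $n_{ij}$ be normalized counts,
$\bar n_{iA}$ and $\bar n_{iB}$ the condition means, and

$$L_i = \log_2 \frac{\bar n_{iA}}{\bar n_{iB}}$$

the observed statistic. The mean, not the median, is used: with a handful of
replicates no observation can be reliably flagged as an outlier, and the
mean keeps the statistic smooth in every count.

**Within-condition pools.** To learn what $L_i$ looks like in the absence of
DE, each condition is split into two halves $A = A_1 \cup A_2$ with
$|A_1| = \lfloor |A|/2 \rfloor$, and the half-vs-half log fold change
$L_i^{A_1 \cup A_2} = \log_2 (\bar n_{iA_1} / \bar n_{iA_2})$ is computed
for every such split. Both halves share a condition, so these values are
pure noise. For $|A| \le 7$ all distinct unordered splits are used (1, 3, 3,
10, 10, 35 splits for $|A| = 2..7$); beyond that, 20 distinct random splits
are drawn from a dedicated seeded generator to bound the cost. Pooling over
splits and both conditions gives per-gene noise collections $L_i^A$ and
$L_i^B$.

**Neighborhoods.** The spread of these noise values depends strongly on
expression level — weakly expressed genes have far wider null fold changes
(the width behaves like $\sqrt{1/\mu + 2\phi}$ under a negative binomial
with mean $\mu$ and dispersion $\phi$). A common null pooled over all genes
is therefore miscalibrated at both ends of the expression range. Instead,
each gene's null pools only its *neighborhood* $N(i)$: the $k$ genes
(default $k = 50$, gene $i$ included at distance zero) whose overall mean
$\bar n_{i,A \cup B}$ is closest to gene $i$'s in absolute difference. The
null is the multiset

$$\mathcal L_i = \bigcup_{i' \in N(i)} L_{i'}^A \cup L_{i'}^B,$$

of size $|N(i)| \, (P_A + P_B)$ where $P_A, P_B$ are the split counts.
Setting $k$ to the number of genes recovers the common-null special case.

**The probability.** A gene's evidence is summarized by the fraction of null
values more extreme than its observed statistic:

$$P(x_i = 0) = \frac{|\{\, l \in \mathcal L_i : |l| > |L_i| \,\}|}{|\mathcal L_i|},$$

with strict inequality, so null values tied in magnitude with $|L_i|$ do not
count as more extreme. Genes are ranked by increasing $P$, and called DE
when $P < 0.1$ (strict). This probability is a relative noise ranking, not a
frequentist p-value; it has no uniformity guarantee under the null and no
FDR calibration (a known limitation, see below).

## Normalization and zero handling

Sequencing depths are estimated by an iterated Poisson goodness-of-fit
scheme: starting from column-total fractions $\hat d_j$, each gene is scored
by $\mathrm{GOF}_i = \sum_j (N_{ij} - \hat d_j N_{i\cdot})^2 / (\hat d_j
N_{i\cdot})$, the least-DE half of genes (smallest score, ties by input
order) is selected, and the depths are re-estimated as $\hat d_j =
\sum_{i \in S} N_{ij} / \sum_{i \in S} \sum_j N_{ij}$, iterating to a
$10^{-10}$ max-norm tolerance with at most 10 passes. The depths sum to 1
by construction; on data exactly proportional across samples they equal the
column-total fractions after one pass. The selection step can oscillate
between two gene subsets on noisy data, in which case the last iterate is
returned with a warning — the depth differences between the two subsets are
negligible in practice. Normalized counts are $n_{ij} = N_{ij} / \hat d_j$.

Two zero rules are applied, in a deliberate order:

1. genes with zero counts in **all** samples are removed *before* depth
   estimation, so the estimator never sees degenerate rows;
2. remaining zero cells are replaced by 0.5 *after* normalization, keyed on
   the raw count being zero, so depth estimation works on untouched counts
   and every log ratio is finite. Replacing normalized rather than raw zeros
   keeps the offset constant (0.5) on the scale the statistic is computed
   on.

## Baselines

Two reference methods ship with the package because the benchmark is about
*why* gene-specific nulls help:

- **Common-null (L, D) baseline** (`run_noiseq_like`): scores each gene by
  the fraction of pooled within-condition sample-pair values $(|l|, |d|)$
  strictly dominated by the observed $(|L_i|, |D_i|)$, where
  $|D_i| = |\bar n_{iA} - \bar n_{iB}|$, pooling *all* genes and all
  within-condition sample pairs into one null (size
  $G\,(\binom{|A|}{2} + \binom{|B|}{2})$). DE is called at probability
  $> 0.8$. This is a faithful implementation of the published description of
  that scheme, not a port of the released NOISeq package (whose smoothing
  and median conventions are out of scope). The dominance count is computed
  exactly by a Fenwick-tree sweep in C++ because the null holds $10^5$–$10^6$
  pairs and each of $2 \times 10^4$ genes queries it.
- **Per-gene permutation baseline** (`run_shgt`): each gene's null is its
  own statistic recomputed under relabelings of samples into
  pseudo-conditions of the original sizes — exhaustive when
  $\binom{|A|+|B|}{|A|} \le 1000$, otherwise 1000 seeded relabelings with
  the identity forced in. The tail uses $\ge$ so the identity relabeling
  guarantees a positive probability (standard permutation-test validity).
  Its published description does not fix the relabeling count, tail
  convention, or call cutoff; all are configurable, with the defaults above
  and a `< 0.1` call cutoff mirroring the main test.

## The simulator

`simulate_sim1()` emulates the standard two-condition negative binomial
benchmark: counts $N_{ij} \sim \mathrm{NB}(\mu_{ij}, \sigma^2_{ij})$ with
$\mu_{ij} = q_i d_j$ and $\sigma^2_{ij} = \mu_{ij} + \phi_i \mu_{ij}^2$,
library factors $d_j \sim U(0.5, 1.5)$, exactly 30% of genes DE of which
exactly 70% up-regulated. The laws not fixed by that description default to
$q_{iA} \sim \mathrm{LogNormal}(\log 200, 1)$, multiplicative DE folds
$\sim U(1.5, 4)$, and $\phi_i \sim U(0.05, 0.5)$ — a realistic bulk RNA-seq
regime: median expression a few hundred counts with heavy upper tail,
biological-replicate-level dispersion (per-gene CV$^2$ of 5–50%), and fold
changes spanning barely-detectable to easy. All three laws are plain
function arguments and can be replaced. `simulate_sim2()` instead resamples
per-gene $(q_{iA}, q_{iB}, \phi_i)$ triples jointly, with replacement, from
an empirical parameter table (e.g. estimated from a real dataset), keeping
rows intact so the empirical mean-dispersion dependence is preserved.

What the generator does **not** emulate: expression-dependent dispersion
trends (dispersion is drawn independently of expression, so the null-width
decline with expression concentrates at low counts and flattens at high
counts, rather than spanning the wide range seen on technical-replicate
real data), outliers and sample contamination, gene length effects,
correlated genes, and isoform structure. Benchmark results on these
simulations therefore demonstrate ranking behavior under a clean NB regime,
not robustness to the full messiness of real libraries.

## Evaluation and the benchmark driver

`auc_score` is the rank-based AUC with midrank ties (identical to exhaustive
DE-vs-non-DE pair counting). `fdr_curve` reports false discoveries among the
top-$k$ genes with stable input-order tie handling. `prf` returns precision,
sensitivity and F-score with `NA` for zero denominators (a method that calls
nothing has undefined precision, not zero). `run_bench` repeats
simulate–test–evaluate over sample sizes and replicates, with each
replicate's seed a pure function `bench_seed(base_seed, size_idx, rep)` so
any single cell can be reproduced in isolation.

Problem sizes: the test suite exercises the full machinery at 1,500–2,000
genes with 2–3 repetitions, which is ample to pin down the ordering
properties it asserts; `scripts/acceptance.R` runs the full protocol of
20,000 genes × 20 repetitions at 2/5/8 replicates per condition, which the
vectorized pools complete in a couple of minutes.

## Numerical conventions

- Half-splits are unordered; for even splits $A_1$ is the half containing
  the lowest-indexed sample, for odd splits the smaller half. Orientation
  only flips the sign of pool values and the probability uses magnitudes,
  so this is purely a determinism convention.
- Random splits are drawn distinct (rejection sampling); requesting more
  random splits than exist falls back to the exhaustive set.
- Neighborhood ties at the boundary break by gene input order; gene $i$ is
  always a member of $N(i)$ even under exact expression ties.
- All seeded draws go through an internal RNG scope that restores the
  caller's `.Random.seed`, so library calls never perturb user scripts.
- Depth estimation requires at least 2 genes and 2 samples and errors on
  all-zero rows rather than silently mishandling them; a sample whose
  counts vanish on the selected half-set is an error, not a zero depth.
- Results are written with six significant digits; reruns at a fixed seed
  are byte-identical.

## Known limitations

- The non-DE probability is uncalibrated: 0.1 is a pragmatic cutoff, not an
  error rate, and no FDR control is provided.
- Exactly two conditions are supported.
- Power at 2 replicates per condition is modest: the within-condition pool
  then contains a single split per condition, so the null rests almost
  entirely on the neighborhood.
- The common-null baseline implements the published *description* of that
  method and should not be used as a stand-in for the released package it
  describes.
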