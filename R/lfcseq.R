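#' Log fold change test statistic
#'
#' \eqn{L_i = \log_2(\bar n_{iA} / \bar n_{iB})}, the log2 ratio of mean
#' normalized counts between the two conditions. Means are guaranteed
#' positive by the 0.5 zero-replacement floor.
#'
#' @param mean_A,mean_B Positive per-gene means of normalized counts.
#' @return Numeric vector of log2 fold changes.
#' @export
lfc_statistic <- function(mean_A, mean_B) {
  if (any(mean_A <= 0) || any(mean_B <= 0)) {
    stop("group means must be strictly positive; was zero replacement applied?")
  }
  log2(mean_A / mean_B)
}

#' Expression neighborhoods by overall mean
#'
#' For each gene i, finds the `k` genes (gene i included, at distance 0)
#' whose overall mean normalized count \eqn{\bar n_{i'A \cup B}} is closest
#' to gene i's, in absolute difference. Ties at the boundary are broken by
#' gene input order. The realized half-width \eqn{\epsilon_i} is the largest
#' selected distance.
#'
#' @param mean_AB Per-gene overall means.
#' @param k Neighborhood size (default 50). `k >= G` selects all genes with a
#'   warning, reducing the method to a single common null.
#' @return List with `members` (G x k integer matrix; row i lists N(i), gene
#'   i first, remaining members in increasing distance) and `epsilon`
#'   (realized half-widths).
#' @export
build_neighborhood <- function(mean_AB, k = 50L) {
  G <- length(mean_AB)
  if (k < 1L) stop("neighborhood size k must be >= 1")
  if (k >= G) {
    if (k > G) warning("k = ", k, " exceeds the number of genes (", G,
                       "); using all genes")
    members <- matrix(seq_len(G), nrow = G, ncol = G, byrow = TRUE)
    eps <- vapply(mean_AB, function(m) max(abs(mean_AB - m)), numeric(1L))
    return(list(members = members, epsilon = eps))
  }
  ord <- order(mean_AB, seq_len(G))
  sm <- mean_AB[ord]
  members <- matrix(0L, nrow = G, ncol = k)
  eps <- numeric(G)
  for (p in seq_len(G)) {
    lo <- max(1L, p - k + 1L)
    hi <- min(G, p + k - 1L)
    cand <- lo:hi
    cand <- cand[cand != p]
    d <- abs(sm[cand] - sm[p])
    oi <- ord[cand]
    pick <- order(d, oi)[seq_len(k - 1L)]
    i <- ord[p]
    members[i, ] <- c(i, oi[pick])
    eps[i] <- if (k > 1L) max(d[pick]) else 0
  }
  list(members = members, epsilon = eps)
}

#' Gene-specific null distribution of log fold changes
#'
#' Pools the within-condition log fold change values of every gene in the
#' neighborhood of gene `i`, across both conditions:
#' \eqn{\mathcal L_i = \bigcup_{i' \in N(i)} L_{i'}^A \cup L_{i'}^B}
#' (a multiset; duplicates are retained).
#'
#' @param i Gene index.
#' @param pool_A,pool_B Genes x partitions pool matrices from
#'   [within_condition_pool()].
#' @param nb Neighborhood from [build_neighborhood()].
#' @return Numeric vector of null log fold changes, of length
#'   \eqn{|N(i)| (P_A + P_B)}.
#' @export
null_distribution <- function(i, pool_A, pool_B, nb) {
  m <- nb$members[i, ]
  c(t(pool_A[m, , drop = FALSE]), t(pool_B[m, , drop = FALSE]))
}

#' Probability of a gene being non-differentially expressed
#'
#' The fraction of null log fold changes strictly larger in magnitude than
#' the observed statistic:
#' \eqn{P(x_i = 0) = |\{l \in \mathcal L_i : |l| > |L_i|\}| / |\mathcal L_i|}.
#' Null values tied in magnitude with \eqn{|L_i|} do not count as more
#' extreme.
#'
#' @param L Observed log2 fold change for the gene.
#' @param null Non-empty numeric vector of null log fold changes.
#' @return A probability in \[0, 1\].
#' @export
prob_nonDE <- function(L, null) {
  if (length(null) == 0L) stop("null distribution is empty")
  sum(abs(null) > abs(L)) / length(null)
}

# Vectorized pass over all genes: counts, per gene i, the null values of its
# neighborhood exceeding |L_i| in magnitude. abs_pool is the G x (P_A + P_B)
# matrix of |within-condition log fold changes|.
all_gene_probs <- function(abs_pool, members, absL) {
  G <- length(absL)
  width <- ncol(abs_pool) * ncol(members)
  probs <- numeric(G)
  for (i in seq_len(G)) {
    probs[i] <- sum(abs_pool[members[i, ], ] > absL[i]) / width
  }
  probs
}

#' Standard deviation of each gene's null distribution
#'
#' Diagnostic for how the spread of the empirical null varies with
#' expression strength: on count data the null of weakly expressed genes is
#' much wider than that of strongly expressed ones, which is the motivation
#' for gene-specific (rather than common) nulls.
#'
#' @inheritParams null_distribution
#' @return Per-gene sample standard deviations (n - 1 denominator) of the
#'   pooled null values.
#' @export
null_pool_sd <- function(pool_A, pool_B, nb) {
  G <- nrow(pool_A)
  full <- cbind(pool_A, pool_B)
  vapply(seq_len(G),
         function(i) stats::sd(full[nb$members[i, ], ]),
         numeric(1L))
}

#' Run the full LFCseq differential-expression test
#'
#' Pipeline: drop all-zero genes, estimate sequencing depths by iterated
#' Poisson goodness of fit, normalize, replace raw-zero cells by 0.5,
#' compute group means and the log2 fold change statistic, build
#' within-condition partition pools for each condition, form each gene's
#' expression neighborhood, pool the neighborhood's within-condition log
#' fold changes into a gene-specific null, and score each gene by the
#' fraction of null values exceeding its observed statistic in magnitude. A
#' gene is called DE when that probability falls strictly below `cutoff`.
#'
#' @param counts Raw count matrix (genes x samples) with gene row names and
#'   sample column names.
#' @param design Named condition vector (two labels) covering all samples,
#'   as from [read_design()].
#' @param k Neighborhood size (number of genes pooled per null).
#' @param max_exhaustive Largest condition size for exhaustive half-split
#'   enumeration.
#' @param n_random Number of random half-splits for larger conditions.
#' @param cutoff Probability cutoff for the DE call (strict `<`).
#' @param seed Seed for the random-partition draws.
#' @param normalize If `FALSE`, skip depth estimation and use the raw counts
#'   as already normalized.
#' @return A data frame with one row per retained gene: `gene_id`, `mean_A`,
#'   `mean_B`, `log2FC`, `prob_nonDE`, `de_call`; attributes `depths`
#'   (per-sample depth factors), `partition_mode` (per condition), and
#'   `n_dropped` (all-zero genes removed).
#' @export
run_lfcseq <- function(counts, design, k = 50L, max_exhaustive = 7L,
                       n_random = 20L, cutoff = 0.1, seed = 1L,
                       normalize = TRUE) {
  groups <- condition_groups(counts, design)
  if (any(lengths(groups) < 2L)) {
    stop("each condition needs at least 2 samples for within-condition ",
         "partitions")
  }
  n_before <- nrow(counts)
  counts <- drop_allzero_genes(counts)
  if (normalize) {
    depths <- estimate_depths(counts)
    norm <- normalize_counts(counts, depths)
  } else {
    depths <- list(d_hat = stats::setNames(rep(1, ncol(counts)),
                                           colnames(counts)))
    norm <- counts
  }
  norm <- replace_zeros(norm, counts)

  colsA <- groups[[1L]]
  colsB <- groups[[2L]]
  mean_A <- rowMeans(norm[, colsA, drop = FALSE])
  mean_B <- rowMeans(norm[, colsB, drop = FALSE])
  mean_AB <- rowMeans(norm)
  L <- lfc_statistic(mean_A, mean_B)

  parts_A <- enumerate_partitions(length(colsA), max_exhaustive, n_random,
                                  seed = seed)
  parts_B <- enumerate_partitions(length(colsB), max_exhaustive, n_random,
                                  seed = seed + 1L)
  pool_A <- within_condition_pool(norm, colsA, parts_A)
  pool_B <- within_condition_pool(norm, colsB, parts_B)
  nb <- build_neighborhood(mean_AB, k = min(k, nrow(counts)))

  probs <- all_gene_probs(abs(cbind(pool_A, pool_B)), nb$members, abs(L))

  res <- data.frame(gene_id = rownames(counts),
                    mean_A = mean_A,
                    mean_B = mean_B,
                    log2FC = L,
                    prob_nonDE = probs,
                    de_call = as.integer(probs < cutoff),
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "depths") <- depths$d_hat
  attr(res, "partition_mode") <- stats::setNames(
    c(parts_A$mode, parts_B$mode), names(groups))
  attr(res, "n_dropped") <- n_before - nrow(counts)
  res
}
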