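#' Absolute difference of group means
#'
#' \eqn{|D_i| = |\bar n_{iA} - \bar n_{iB}|}, the second statistic of the
#' common-null baseline.
#'
#' @param mean_A,mean_B Per-gene means of normalized, zero-replaced counts.
#' @return Non-negative numeric vector.
#' @export
abs_difference <- function(mean_A, mean_B) {
  abs(mean_A - mean_B)
}

#' Common joint null of (log fold change, absolute difference) pairs
#'
#' For every unordered pair of samples within the same condition and for
#' every gene, computes the log2 fold change and the absolute difference of
#' their normalized counts. All pairs are pooled across genes into a single
#' null shared by every gene, of size
#' \eqn{G \, (\binom{|A|}{2} + \binom{|B|}{2})}.
#'
#' @param norm Normalized, zero-replaced matrix (strictly positive).
#' @param cols_A,cols_B Column indices of the two conditions.
#' @return List with `abs_l` and `abs_d`, the pooled \eqn{|l|} and
#'   \eqn{|d|} values, and `size`.
#' @export
joint_null <- function(norm, cols_A, cols_B) {
  if (any(norm <= 0)) {
    stop("joint null requires a strictly positive matrix; apply zero ",
         "replacement first")
  }
  pair_vals <- function(cols) {
    if (length(cols) < 2L) return(list(l = numeric(0), d = numeric(0)))
    prs <- utils::combn(cols, 2L)
    l <- vector("list", ncol(prs))
    d <- vector("list", ncol(prs))
    for (p in seq_len(ncol(prs))) {
      a <- norm[, prs[1L, p]]
      b <- norm[, prs[2L, p]]
      l[[p]] <- log2(a / b)
      d[[p]] <- abs(a - b)
    }
    list(l = unlist(l, use.names = FALSE), d = unlist(d, use.names = FALSE))
  }
  pa <- pair_vals(cols_A)
  pb <- pair_vals(cols_B)
  abs_l <- abs(c(pa$l, pb$l))
  abs_d <- c(pa$d, pb$d)
  list(abs_l = abs_l, abs_d = abs_d, size = length(abs_l))
}

#' Common-null probability of differential expression
#'
#' The fraction of null pairs strictly dominated by the observed statistics
#' in both coordinates:
#' \deqn{P(x_i = 1) = |\{(l, d) : |l| < |L_i|, |d| < |D_i|\}| / |(L, D)|.}
#' Unlike the gene-specific LFCseq null, one pooled null serves all genes.
#'
#' @param L Observed log2 fold change(s).
#' @param D Observed absolute difference(s) of group means.
#' @param null Joint null from [joint_null()].
#' @return Probabilities in \[0, 1\], one per element of `L`.
#' @export
noiseq_prob_DE <- function(L, D, null) {
  if (null$size == 0L) stop("joint null is empty")
  count_dominated(null$abs_l, null$abs_d, abs(L), abs(D)) / null$size
}

#' Run the common-null (L, D) baseline test
#'
#' Shares the preprocessing of [run_lfcseq()] (all-zero gene removal, depth
#' normalization, 0.5 zero replacement) but scores each gene against a single
#' joint null of per-sample-pair (log fold change, absolute difference)
#' values pooled over all genes. A gene is called DE when its probability of
#' differential expression exceeds `cutoff` (strict `>`).
#'
#' @inheritParams run_lfcseq
#' @param cutoff DE probability cutoff (default 0.8).
#' @return Data frame with columns `gene_id`, `mean_A`, `mean_B`, `log2FC`,
#'   `abs_diff`, `prob_DE`, `de_call`.
#' @export
run_noiseq_like <- function(counts, design, cutoff = 0.8, normalize = TRUE) {
  groups <- condition_groups(counts, design)
  if (any(lengths(groups) < 2L)) {
    stop("each condition needs at least 2 samples to form within-condition ",
         "pairs")
  }
  counts <- drop_allzero_genes(counts)
  if (normalize) {
    norm <- normalize_counts(counts, estimate_depths(counts))
  } else {
    norm <- counts
  }
  norm <- replace_zeros(norm, counts)
  mean_A <- rowMeans(norm[, groups[[1L]], drop = FALSE])
  mean_B <- rowMeans(norm[, groups[[2L]], drop = FALSE])
  L <- lfc_statistic(mean_A, mean_B)
  D <- abs_difference(mean_A, mean_B)
  null <- joint_null(norm, groups[[1L]], groups[[2L]])
  probs <- noiseq_prob_DE(L, D, null)
  data.frame(gene_id = rownames(counts),
             mean_A = mean_A, mean_B = mean_B,
             log2FC = L, abs_diff = D,
             prob_DE = probs,
             de_call = as.integer(probs > cutoff),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Relabelings of all samples into pseudo-conditions of sizes (nA, nB):
# matrix with one column per relabeling listing the pseudo-A sample indices.
# The identity relabeling (true condition A) is always column 1.
shgt_relabelings <- function(cols_A, cols_B, max_exhaustive = 1000L,
                             n_random = 1000L, seed = 1L) {
  all_cols <- c(cols_A, cols_B)
  n <- length(all_cols)
  nA <- length(cols_A)
  if (choose(n, nA) <= max_exhaustive) {
    combos <- utils::combn(all_cols, nA)
    id <- which(apply(combos, 2L, function(s) setequal(s, cols_A)))[1L]
    combos[, c(id, setdiff(seq_len(ncol(combos)), id)), drop = FALSE]
  } else {
    rnd <- with_seed(seed, {
      replicate(n_random - 1L, sort(sample(all_cols, nA)))
    })
    cbind(sort(cols_A), rnd)
  }
}

#' Per-gene permutation-test probability (simple hypergeometric test)
#'
#' Baseline that builds each gene's null by relabeling that gene's own
#' samples into pseudo-conditions of the original sizes, rather than by
#' pooling a neighborhood of genes. The probability of the gene being
#' non-DE is the fraction of relabelings whose log fold change is at least
#' as extreme as the observed one (`>=`, so the identity relabeling
#' guarantees a probability of at least 1/#relabelings). Relabelings are
#' exhaustive when \eqn{\binom{|A|+|B|}{|A|}} does not exceed
#' `max_exhaustive`, otherwise `n_random` seeded draws (identity included).
#'
#' @param x One gene's normalized, zero-replaced values across all samples.
#' @param cols_A,cols_B Indices of the two conditions' samples within `x`.
#' @param max_exhaustive Relabeling count up to which enumeration is
#'   exhaustive.
#' @param n_random Number of relabelings drawn otherwise.
#' @param seed Seed for random relabelings.
#' @return Probability of the gene being non-DE, in (0, 1\].
#' @export
shgt_prob <- function(x, cols_A, cols_B, max_exhaustive = 1000L,
                      n_random = 1000L, seed = 1L) {
  if (length(cols_A) + length(cols_B) < 4L) {
    stop("permutation baseline needs at least 4 samples in total")
  }
  relab <- shgt_relabelings(cols_A, cols_B, max_exhaustive, n_random, seed)
  all_cols <- c(cols_A, cols_B)
  null <- apply(relab, 2L, function(g1) {
    g2 <- setdiff(all_cols, g1)
    log2(mean(x[g1]) / mean(x[g2]))
  })
  L_obs <- log2(mean(x[cols_A]) / mean(x[cols_B]))
  mean(abs(null) >= abs(L_obs))
}

#' Run the per-gene permutation baseline on a whole matrix
#'
#' Vectorized form of [shgt_prob()] sharing the preprocessing of
#' [run_lfcseq()]. All genes share the same set of relabelings.
#'
#' @inheritParams run_lfcseq
#' @param max_exhaustive Relabeling count up to which enumeration is
#'   exhaustive.
#' @param n_random Number of random relabelings otherwise.
#' @param cutoff Non-DE probability cutoff for the DE call (strict `<`).
#' @return Data frame with columns `gene_id`, `mean_A`, `mean_B`, `log2FC`,
#'   `prob_nonDE`, `de_call`.
#' @export
run_shgt <- function(counts, design, max_exhaustive = 1000L,
                     n_random = 1000L, cutoff = 0.1, seed = 1L,
                     normalize = TRUE) {
  groups <- condition_groups(counts, design)
  if (sum(lengths(groups)) < 4L) {
    stop("permutation baseline needs at least 4 samples in total")
  }
  counts <- drop_allzero_genes(counts)
  if (normalize) {
    norm <- normalize_counts(counts, estimate_depths(counts))
  } else {
    norm <- counts
  }
  norm <- replace_zeros(norm, counts)
  cols_A <- groups[[1L]]
  cols_B <- groups[[2L]]
  relab <- shgt_relabelings(cols_A, cols_B, max_exhaustive, n_random, seed)
  all_cols <- c(cols_A, cols_B)
  n <- length(all_cols)
  R <- ncol(relab)
  ind <- matrix(0, nrow = ncol(norm), ncol = R)
  for (r in seq_len(R)) ind[relab[, r], r] <- 1
  keep <- rep(0, ncol(norm))
  keep[all_cols] <- 1
  ind2 <- keep - ind
  m1 <- (norm %*% ind) / length(cols_A)
  m2 <- (norm %*% ind2) / length(cols_B)
  Lmat <- abs(log2(m1 / m2))
  L_obs <- Lmat[, 1L]
  probs <- rowMeans(Lmat >= L_obs)
  mean_A <- rowMeans(norm[, cols_A, drop = FALSE])
  mean_B <- rowMeans(norm[, cols_B, drop = FALSE])
  data.frame(gene_id = rownames(counts),
             mean_A = mean_A, mean_B = mean_B,
             log2FC = lfc_statistic(mean_A, mean_B),
             prob_nonDE = probs,
             de_call = as.integer(probs < cutoff),
             row.names = NULL, stringsAsFactors = FALSE)
}
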