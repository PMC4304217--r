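#' Poisson goodness-of-fit statistic per gene
#'
#' Measures how far each gene's counts deviate from exact proportionality to
#' the sequencing depths: under a Poisson model with gene total \eqn{N_{i.}}
#' split across samples in proportion \eqn{\hat d_j}, the chi-squared-type
#' score is
#' \deqn{GOF_i = \sum_j (N_{ij} - \hat d_j N_{i.})^2 / (\hat d_j N_{i.}).}
#' Genes least differentially expressed between conditions have the smallest
#' deviation from cross-sample proportionality, hence the smallest score.
#'
#' @param counts Count matrix with no all-zero rows.
#' @param d Positive per-sample depth fractions, summing to 1.
#' @return Numeric vector of non-negative per-gene statistics.
#' @export
poisson_gof <- function(counts, d) {
  if (any(d <= 0)) stop("depth factors must be strictly positive")
  row_tot <- rowSums(counts)
  if (any(row_tot == 0)) {
    stop("genes with zero total count must be dropped before computing the ",
         "goodness-of-fit statistic")
  }
  expected <- outer(row_tot, d)
  rowSums((counts - expected)^2 / expected)
}

#' Estimate per-sample sequencing depths by iterated goodness of fit
#'
#' Starts from column-total fractions and alternates two steps: score every
#' gene with [poisson_gof()] against the current depths, then re-estimate the
#' depths from the half of the genes with the smallest score (the least
#' differentially expressed half),
#' \deqn{\hat d_j = \sum_{i \in S} N_{ij} / \sum_{i \in S} \sum_j N_{ij}.}
#' Iteration stops when the depths move by less than `tol` in the max norm or
#' after `max_iter` passes (with a warning). Ties in the score are broken by
#' gene input order. The depths sum to 1 by construction.
#'
#' @param counts Count matrix, at least 2 genes and 2 samples, no all-zero
#'   rows.
#' @param max_iter Maximum number of re-selection passes.
#' @param tol Convergence tolerance on \eqn{\max_j |\Delta \hat d_j|}.
#' @return A list with elements `d_hat` (named per-sample depths),
#'   `selected_genes` (gene ids of the final least-DE half), `n_iter`, and
#'   `converged`.
#' @export
estimate_depths <- function(counts, max_iter = 10L, tol = 1e-10) {
  G <- nrow(counts)
  J <- ncol(counts)
  if (G < 2L || J < 2L) {
    stop("depth estimation needs at least 2 genes and 2 samples")
  }
  if (any(rowSums(counts) == 0)) {
    stop("drop all-zero genes before estimating depths")
  }
  d <- colSums(counts) / sum(counts)
  n_half <- floor(G / 2)
  sel <- integer(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    gof <- poisson_gof(counts, d)
    sel <- order(gof, seq_len(G))[seq_len(n_half)]
    sub <- counts[sel, , drop = FALSE]
    d_new <- colSums(sub) / sum(sub)
    if (any(d_new <= 0)) {
      stop("selected gene subset leaves a sample with zero total count; ",
           "depths are undefined")
    }
    delta <- max(abs(d_new - d))
    d <- d_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("depth estimation did not converge in ", max_iter,
            " iterations; returning last iterate")
  }
  list(d_hat = stats::setNames(d, colnames(counts)),
       selected_genes = rownames(counts)[sort(sel)],
       n_iter = iter, converged = converged)
}

#' Normalize counts by estimated sequencing depths
#'
#' @param counts Count matrix.
#' @param d Positive per-sample depth factors (vector, or the list returned
#'   by [estimate_depths()]).
#' @return Matrix of normalized counts \eqn{n_{ij} = N_{ij} / \hat d_j}.
#' @export
normalize_counts <- function(counts, d) {
  if (is.list(d)) d <- d$d_hat
  if (length(d) != ncol(counts)) {
    stop("need one depth factor per sample")
  }
  if (any(d <= 0)) stop("depth factors must be strictly positive")
  sweep(counts, 2L, d, "/")
}
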