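#' Enumerate half-splits of one condition's samples
#'
#' Splits `n` samples into two groups of sizes \eqn{(\lfloor n/2 \rfloor,
#' \lceil n/2 \rceil)}. Partitions are unordered: \eqn{(A_1, A_2)} and
#' \eqn{(A_2, A_1)} count once. For even `n` the orientation is fixed by
#' placing the first sample in \eqn{A_1}; for odd `n`, \eqn{A_1} is the
#' smaller group. When `n <= max_exhaustive` all partitions are listed; for
#' larger `n`, exactly `n_random` distinct partitions are drawn uniformly
#' without replacement using `seed` (the draw is reproducible and does not
#' disturb the caller's RNG). If fewer than `n_random` distinct partitions
#' exist, the full exhaustive set is returned instead.
#'
#' @param n Number of samples in the condition (>= 2).
#' @param max_exhaustive Largest `n` for which all partitions are enumerated.
#' @param n_random Number of random partitions drawn when `n` exceeds
#'   `max_exhaustive`.
#' @param seed Integer seed for the random-partition draw.
#' @return A list of class `"lfcseq_partitions"` with elements `partitions`
#'   (list of `list(A1 =, A2 =)` index vectors into `1:n`), `mode`
#'   (`"exhaustive"` or `"random"`), `n`, and `seed`.
#' @export
enumerate_partitions <- function(n, max_exhaustive = 7L, n_random = 20L,
                                 seed = 1L) {
  if (n < 2L) stop("need at least 2 samples to partition a condition")
  h <- as.integer(floor(n / 2))
  all_idx <- seq_len(n)
  if (n <= max_exhaustive || n_half_partitions(n) <= n_random) {
    combos <- utils::combn(n, h, simplify = FALSE)
    if (n %% 2L == 0L) {
      combos <- Filter(function(s) 1L %in% s, combos)
    }
    parts <- lapply(combos, function(s) list(A1 = s, A2 = setdiff(all_idx, s)))
    mode <- "exhaustive"
  } else {
    parts <- vector("list", n_random)
    seen <- character(0)
    got <- 0L
    with_seed(seed, {
      while (got < n_random) {
        s <- sort(sample.int(n, h))
        if (n %% 2L == 0L && !(1L %in% s)) s <- setdiff(all_idx, s)
        key <- paste(s, collapse = ",")
        if (!(key %in% seen)) {
          got <- got + 1L
          seen[got] <- key
          parts[[got]] <- list(A1 = s, A2 = setdiff(all_idx, s))
        }
      }
    })
    mode <- "random"
  }
  structure(list(partitions = parts, mode = mode, n = n, seed = seed),
            class = "lfcseq_partitions")
}

#' Within-condition log fold change pool
#'
#' For every gene and every half-split \eqn{A = A_1 \cup A_2} of one
#' condition's samples, computes
#' \eqn{L_i^{A_1 \cup A_2} = \log_2(\bar n_{iA_1} / \bar n_{iA_2})} on the
#' normalized, zero-replaced matrix. Because both halves come from the same
#' condition, these values carry no differential-expression signal and form
#' the raw material of the empirical null.
#'
#' @param norm Normalized matrix with zeros already replaced (all entries
#'   positive).
#' @param cols Column indices of the condition's samples.
#' @param parts Partition set from [enumerate_partitions()] with `n ==
#'   length(cols)`.
#' @return A genes x partitions matrix of log2 fold changes.
#' @export
within_condition_pool <- function(norm, cols, parts) {
  stopifnot(inherits(parts, "lfcseq_partitions"), parts$n == length(cols))
  X <- norm[, cols, drop = FALSE]
  if (any(X <= 0)) {
    stop("pool computation requires a strictly positive matrix; apply ",
         "zero replacement first")
  }
  P <- length(parts$partitions)
  ind1 <- matrix(0, nrow = length(cols), ncol = P)
  ind2 <- matrix(0, nrow = length(cols), ncol = P)
  for (p in seq_len(P)) {
    ind1[parts$partitions[[p]]$A1, p] <- 1
    ind2[parts$partitions[[p]]$A2, p] <- 1
  }
  size1 <- colSums(ind1)
  size2 <- colSums(ind2)
  mean1 <- sweep(X %*% ind1, 2L, size1, "/")
  mean2 <- sweep(X %*% ind2, 2L, size2, "/")
  log2(mean1 / mean2)
}
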