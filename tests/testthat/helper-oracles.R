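# Independent brute-force oracles used to cross-check the package's
# vectorized implementations. Deliberately written as plain loops over
# definitions, sharing no code with the package internals.

# Fraction of null values strictly larger in magnitude than |L|.
bf_prob_nonDE <- function(L, null) {
  n_more_extreme <- 0L
  for (l in null) {
    if (abs(l) > abs(L)) n_more_extreme <- n_more_extreme + 1L
  }
  n_more_extreme / length(null)
}

# Fraction of (l, d) null pairs strictly dominated in both coordinates.
bf_noiseq_prob <- function(L, D, null_l, null_d) {
  cnt <- 0L
  for (j in seq_along(null_l)) {
    if (abs(null_l[j]) < abs(L) && abs(null_d[j]) < abs(D)) cnt <- cnt + 1L
  }
  cnt / length(null_l)
}

# AUC as the exhaustive probability that a DE gene outranks a non-DE gene,
# ties counting one half.
bf_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  s <- 0
  for (a in pos) {
    for (b in neg) {
      s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  s / (length(pos) * length(neg))
}

# All unordered half-splits of 1:n into sizes (floor(n/2), ceil(n/2)),
# enumerated over the full power set and deduplicated by canonical key.
bf_partitions <- function(n) {
  h <- floor(n / 2)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  seen <- character(0)
  parts <- list()
  for (r in seq_len(nrow(grid))) {
    in1 <- which(unlist(grid[r, ]))
    if (length(in1) != h) next
    in2 <- setdiff(seq_len(n), in1)
    key <- if (n %% 2 == 0) {
      paste(sort(vapply(list(in1, in2), paste, "", collapse = ",")),
            collapse = "|")
    } else {
      paste(in1, collapse = ",")
    }
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      parts[[length(parts) + 1L]] <- list(A1 = in1, A2 = in2)
    }
  }
  parts
}

# k nearest genes (self included) by |mean - mean_i|, ties by input order.
bf_neighborhood <- function(means, i, k) {
  d <- abs(means - means[i])
  d[i] <- -Inf  # self always first
  sort(order(d, seq_along(means))[seq_len(k)])
}

# Depth estimation re-derived from its definition with explicit loops.
bf_depths <- function(counts, max_iter = 10, tol = 1e-10) {
  G <- nrow(counts); J <- ncol(counts)
  d <- colSums(counts) / sum(counts)
  for (it in seq_len(max_iter)) {
    gof <- numeric(G)
    for (i in seq_len(G)) {
      tot <- sum(counts[i, ])
      for (j in seq_len(J)) {
        e <- d[j] * tot
        gof[i] <- gof[i] + (counts[i, j] - e)^2 / e
      }
    }
    sel <- order(gof, seq_len(G))[seq_len(floor(G / 2))]
    d_new <- numeric(J)
    for (j in seq_len(J)) d_new[j] <- sum(counts[sel, j])
    d_new <- d_new / sum(d_new)
    if (max(abs(d_new - d)) < tol) return(d_new)
    d <- d_new
  }
  d
}

# Tiny deterministic count matrix fixture.
toy_counts <- function(G = 6, J = 4, seed = 11) {
  set.seed(seed)
  m <- matrix(rpois(G * J, 50), nrow = G,
              dimnames = list(paste0("g", seq_len(G)),
                              paste0("s", seq_len(J))))
  m
}

toy_design <- function(J = 4) {
  stats::setNames(rep(c("A", "B"), each = J / 2), paste0("s", seq_len(J)))
}
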