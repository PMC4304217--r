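test_that("log fold change statistic is log2 of the mean ratio", {
  expect_equal(lfc_statistic(5, 5), 0)
  expect_equal(lfc_statistic(8, 2), 2)
  expect_equal(lfc_statistic(0.5, 8), -4)
  expect_error(lfc_statistic(0, 1), "positive")
})

test_that("neighborhoods pick the k nearest genes with self included", {
  means <- c(1, 2, 3, 10)
  nb <- build_neighborhood(means, k = 2)
  expect_identical(sort(nb$members[2, ]), c(1L, 2L))  # tie 1 vs 3 -> input order
  expect_identical(nb$members[4, 1], 4L)
  expect_equal(nb$epsilon[4], 7)

  nb1 <- build_neighborhood(means, k = 1)
  expect_identical(nb1$members[, 1], 1:4)
  expect_equal(nb1$epsilon, rep(0, 4))

  # k = G uses all genes; k > G warns
  nbG <- build_neighborhood(means, k = 4)
  expect_identical(sort(nbG$members[1, ]), 1:4)
  expect_warning(build_neighborhood(means, k = 9), "exceeds")
})

test_that("neighborhoods match the brute-force nearest scan on random cases", {
  set.seed(23)
  for (case in 1:20) {
    G <- sample(5:60, 1)
    k <- sample(seq_len(G), 1)
    means <- round(rlnorm(G, 3, 1.5), sample(c(0, 1, 3), 1))  # ties possible
    nb <- build_neighborhood(means, k = k)
    for (i in sample(G, min(G, 8))) {
      expect_identical(sort(nb$members[i, ]), bf_neighborhood(means, i, k))
    }
  }
})

test_that("null distributions pool the neighborhood's partition values", {
  set.seed(5)
  norm <- matrix(runif(8 * 8, 1, 50), 8, 8)
  pool_A <- within_condition_pool(norm, 1:4, enumerate_partitions(4))
  pool_B <- within_condition_pool(norm, 5:8, enumerate_partitions(4))
  nb <- build_neighborhood(rowMeans(norm), k = 3)
  null5 <- null_distribution(5, pool_A, pool_B, nb)
  expect_length(null5, 3 * (3 + 3))
  expect_setequal(null5, c(pool_A[nb$members[5, ], ], pool_B[nb$members[5, ], ]))

  # k = 1: the null is the gene's own pools
  nb1 <- build_neighborhood(rowMeans(norm), k = 1)
  expect_setequal(null_distribution(2, pool_A, pool_B, nb1),
                  c(pool_A[2, ], pool_B[2, ]))
})

test_that("null sizes follow k x (partitions_A + partitions_B)", {
  set.seed(6)
  G <- 60
  norm <- matrix(runif(G * 10, 1, 50), G, 10)
  pool_A <- within_condition_pool(norm, 1:5, enumerate_partitions(5))
  pool_B <- within_condition_pool(norm, 6:10, enumerate_partitions(5))
  nb <- build_neighborhood(rowMeans(norm), k = 50)
  expect_length(null_distribution(1, pool_A, pool_B, nb), 50 * (10 + 10))

  pool_A2 <- within_condition_pool(norm, 1:2, enumerate_partitions(2))
  pool_B2 <- within_condition_pool(norm, 3:4, enumerate_partitions(2))
  expect_length(null_distribution(1, pool_A2, pool_B2, nb), 50 * (1 + 1))
})

test_that("prob_nonDE counts strictly more extreme null values", {
  expect_equal(prob_nonDE(1, c(-3, 2, 0.5, -1)), 0.5)
  expect_equal(prob_nonDE(10, c(-3, 2, 0.5)), 0)
  expect_equal(prob_nonDE(0, c(-3, 2, 0.5)), 1)
  expect_equal(prob_nonDE(2, c(2, -2, 3)), 1 / 3)  # magnitude ties excluded
  expect_error(prob_nonDE(1, numeric(0)), "empty")
})

test_that("prob_nonDE equals the brute-force count and is monotone in |L|", {
  set.seed(41)
  for (case in 1:50) {
    null <- rnorm(sample(3:40, 1))
    L <- rnorm(1)
    expect_identical(prob_nonDE(L, null), bf_prob_nonDE(L, null))
    Ls <- sort(abs(rnorm(10)))
    ps <- vapply(Ls, prob_nonDE, numeric(1), null = null)
    expect_true(all(diff(ps) <= 0))
  }
})

test_that("identical conditions produce zero fold changes and no DE calls", {
  set.seed(8)
  half <- matrix(rpois(100 * 2, 30), 100, 2)
  counts <- cbind(half, half)
  dimnames(counts) <- list(paste0("g", 1:100), c("A1", "A2", "B1", "B2"))
  design <- stats::setNames(c("A", "A", "B", "B"), colnames(counts))
  res <- suppressMessages(run_lfcseq(counts, design))
  expect_equal(res$log2FC, rep(0, nrow(res)))
  expect_equal(sum(res$de_call), 0L)
})

test_that("strong fold changes are ranked perfectly (AUC 1)", {
  set.seed(12)
  G <- 200
  q <- rlnorm(G, log(200), 0.5)
  truth <- integer(G); truth[sample(G, 20)] <- 1L
  qB <- ifelse(truth == 1L, q * 16, q)
  counts <- cbind(matrix(rpois(G * 5, q), G, 5),
                  matrix(rpois(G * 5, qB), G, 5))
  dimnames(counts) <- list(paste0("g", 1:G),
                           c(paste0("A", 1:5), paste0("B", 1:5)))
  design <- stats::setNames(rep(c("A", "B"), each = 5), colnames(counts))
  res <- suppressMessages(run_lfcseq(counts, design))
  expect_equal(auc_score(1 - res$prob_nonDE, truth), 1.0)
  # the 20 true genes occupy the 20 smallest probabilities
  expect_setequal(order(res$prob_nonDE, decreasing = FALSE)[1:20],
                  which(truth == 1L))
})

test_that("the pipeline is deterministic for a fixed seed", {
  set.seed(3)
  counts <- matrix(rnbinom(300 * 16, mu = 80, size = 5), 300, 16,
                   dimnames = list(paste0("g", 1:300),
                                   c(paste0("A", 1:8), paste0("B", 1:8))))
  design <- stats::setNames(rep(c("A", "B"), each = 8), colnames(counts))
  r1 <- suppressMessages(run_lfcseq(counts, design, seed = 4))
  r2 <- suppressMessages(run_lfcseq(counts, design, seed = 4))
  expect_identical(r1, r2)
  r3 <- suppressMessages(run_lfcseq(counts, design, seed = 5))
  expect_false(identical(r1$prob_nonDE, r3$prob_nonDE))
})

test_that("k = G degenerates to one common null shared by all genes", {
  set.seed(9)
  G <- 40
  counts <- matrix(rnbinom(G * 8, mu = 60, size = 3) + 1, G, 8,
                   dimnames = list(paste0("g", 1:G),
                                   c(paste0("A", 1:4), paste0("B", 1:4))))
  design <- stats::setNames(rep(c("A", "B"), each = 4), colnames(counts))
  res <- run_lfcseq(counts, design, k = G)
  # permuting gene order leaves each gene's probability unchanged
  perm <- sample(G)
  res_p <- run_lfcseq(counts[perm, ], design, k = G)
  expect_equal(res_p$prob_nonDE[match(res$gene_id, res_p$gene_id)],
               res$prob_nonDE)
})

test_that("null pool spread shrinks with expression strength", {
  p <- sim_params(n_genes = 1500, n_A = 5, n_B = 5, seed = 21)
  sim <- simulate_sim1(p)
  counts <- suppressMessages(drop_allzero_genes(sim$counts))
  norm <- replace_zeros(normalize_counts(counts, estimate_depths(counts)),
                        counts)
  groups <- condition_groups(counts, sim$design)
  pool_A <- within_condition_pool(norm, groups[[1]], enumerate_partitions(5))
  pool_B <- within_condition_pool(norm, groups[[2]], enumerate_partitions(5))
  mean_AB <- rowMeans(norm)
  nb <- build_neighborhood(mean_AB, k = 50)
  sds <- null_pool_sd(pool_A, pool_B, nb)
  # closed-form checks
  expect_equal(null_pool_sd(matrix(1, 2, 3), matrix(1, 2, 2),
                            build_neighborhood(c(1, 1), k = 1)),
               c(0, 0))
  expect_equal(null_pool_sd(matrix(c(-1, 1), 1, 2), matrix(numeric(0), 1, 0),
                            build_neighborhood(1, k = 1)),
               sqrt(2))
  # qualitative trend: null width shrinks as expression grows. Under
  # constant NB dispersion the decline concentrates at low expression
  # (width ~ sqrt(1/mu + 2*phi)), so compare the extremes and the overall
  # rank association rather than demanding strict bin-wise monotonicity.
  dec <- cut(rank(mean_AB, ties.method = "first"), 10, labels = FALSE)
  med <- tapply(sds, dec, median)
  expect_gt(med[1], med[10])
  expect_lt(cor(mean_AB, sds, method = "spearman"), 0)
})
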