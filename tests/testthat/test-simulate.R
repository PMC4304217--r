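test_that("negative binomial draws reproduce the mean-variance form", {
  set.seed(61)
  x <- nb_draw(1e5, mu = 100, phi = 0.1)
  expect_equal(mean(x), 100, tolerance = 0.03)
  expect_equal(var(x), 1100, tolerance = 0.05)  # mu + phi * mu^2

  y <- nb_draw(1e5, mu = 100, phi = 0)          # Poisson limit
  expect_equal(mean(y), 100, tolerance = 0.03)
  expect_equal(var(y), 100, tolerance = 0.05)

  expect_error(nb_draw(5, mu = 0, phi = 0.1), "positive")
  expect_error(nb_draw(5, mu = 10, phi = -1), "non-negative")
})

test_that("parametric simulation fixes exact DE and up-regulation counts", {
  p <- sim_params(n_genes = 2000, n_A = 3, n_B = 3, seed = 2)
  sim <- simulate_sim1(p)
  expect_identical(sum(sim$truth), 600L)                  # 30% DE
  expect_identical(sum(sim$direction == "up"), 420L)      # 70% of DE up
  expect_identical(sum(sim$direction == "down"), 180L)
  expect_identical(dim(sim$counts), c(2000L, 6L))
  expect_identical(unname(sim$design), rep(c("A", "B"), each = 3))
  # non-DE genes keep identical expression parameters across conditions
  expect_equal(sim$q_A[sim$truth == 0], sim$q_B[sim$truth == 0])
  expect_true(all(sim$q_B[sim$direction == "up"] >
                  sim$q_A[sim$direction == "up"]))
  expect_true(all(sim$q_B[sim$direction == "down"] <
                  sim$q_A[sim$direction == "down"]))

  none <- simulate_sim1(sim_params(n_genes = 100, prop_DE = 0, seed = 3))
  expect_identical(sum(none$truth), 0L)
  expect_equal(none$q_A, none$q_B)
})

test_that("simulated datasets are pure functions of the seed", {
  p <- sim_params(n_genes = 300, n_A = 2, n_B = 2, seed = 9)
  s1 <- simulate_sim1(p)
  s2 <- simulate_sim1(p)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_sim1(sim_params(n_genes = 300, n_A = 2, n_B = 2, seed = 10))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("library factors act multiplicatively on expected column totals", {
  p <- sim_params(n_genes = 4000, n_A = 2, n_B = 2, prop_DE = 0,
                  dispersion_law = function(n) rep(0, n), seed = 4)
  sim <- simulate_sim1(p)
  tot <- colSums(sim$counts)
  expected <- sum(sim$q_A) * sim$depth
  expect_equal(unname(tot / expected), rep(1, 4), tolerance = 0.05)
})

test_that("for non-DE genes, depth-corrected means recover q in both conditions", {
  p <- sim_params(n_genes = 400, n_A = 50, n_B = 50, prop_DE = 0, seed = 13,
                  dispersion_law = function(n) runif(n, 0.01, 0.05))
  sim <- simulate_sim1(p)
  norm <- sweep(sim$counts, 2, sim$depth, "/")
  relA <- rowMeans(norm[, 1:50]) / sim$q_A
  relB <- rowMeans(norm[, 51:100]) / sim$q_A
  expect_equal(median(relA), 1, tolerance = 0.03)
  expect_equal(median(relB), 1, tolerance = 0.03)
})

test_that("empirical resampling keeps parameter rows intact", {
  tab <- data.frame(qA = c(10, 20, 5), qB = c(10, 80, 5),
                    phi = c(0.2, 0.1, 0.4))
  p <- sim_params(n_genes = 500, n_A = 3, n_B = 3, seed = 6)
  sim <- simulate_sim2(tab, p)
  key <- paste(sim$q_A, sim$q_B, sim$phi)
  ref <- paste(tab$qA, tab$qB, tab$phi)
  expect_true(all(key %in% ref))
  expect_identical(unname(sim$truth), as.integer(sim$q_A != sim$q_B))

  one <- simulate_sim2(data.frame(qA = 10, qB = 10, phi = 0.2), p)
  expect_identical(sum(one$truth), 0L)
  expect_equal(unname(one$q_A), rep(10, 500))

  s1 <- simulate_sim2(tab, p)
  expect_identical(sim$counts, s1$counts)  # seeded resampling reproducible

  expect_error(simulate_sim2(data.frame(qA = 0, qB = 1, phi = 0.1), p),
               "positive")
  expect_error(simulate_sim2(data.frame(qA = 1, qB = 1, phi = -0.1), p),
               "non-negative")
  expect_error(simulate_sim2(tab[0, ], p), "empty")
})

test_that("simulated datasets round-trip through the TSV writers", {
  p <- sim_params(n_genes = 40, n_A = 2, n_B = 2, seed = 8)
  sim <- simulate_sim1(p)
  prefix <- file.path(withr::local_tempdir(), "sim")
  paths <- write_sim(sim, prefix)
  counts <- read_counts(paste0(prefix, "_counts.tsv"))
  expect_equal(unname(counts), unname(sim$counts))
  design <- read_design(paste0(prefix, "_design.tsv"))
  expect_identical(design, sim$design)
  truth <- read.delim(paste0(prefix, "_truth.tsv"))
  expect_identical(truth$de, unname(sim$truth))
})
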