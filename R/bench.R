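#' Deterministic per-replicate seed
#'
#' Pure function of the base seed, the sample-size index, and the replicate
#' index, so that any single cell of a benchmark summary can be reproduced
#' in isolation. Kept within 32-bit integer range.
#'
#' @param base_seed Integer base seed.
#' @param size_idx Index of the sample-size setting (1-based).
#' @param rep Replicate index (1-based).
#' @return Integer seed.
#' @export
bench_seed <- function(base_seed, size_idx, rep) {
  as.integer((as.double(base_seed) * 7919 + size_idx * 611953 + rep * 104729)
             %% 2147483647)
}

# Run one method on a simulated dataset, returning score/call vectors on the
# sim's truth scale (larger score = more DE evidence).
run_method <- function(method, sim, k = 50L, seed = 1L) {
  counts <- sim$counts
  design <- sim$design
  switch(method,
    "lfcseq" = {
      res <- run_lfcseq(counts, design, k = k, seed = seed)
      list(scores = 1 - res$prob_nonDE, calls = res$de_call,
           gene_id = res$gene_id)
    },
    "noiseq-like" = {
      res <- run_noiseq_like(counts, design)
      list(scores = res$prob_DE, calls = res$de_call, gene_id = res$gene_id)
    },
    "shgt" = {
      res <- run_shgt(counts, design, seed = seed)
      list(scores = 1 - res$prob_nonDE, calls = res$de_call,
           gene_id = res$gene_id)
    },
    stop("unknown method '", method, "'"))
}

#' Repeated simulate-test-evaluate benchmark
#'
#' For every combination of sample size and method, simulates `n_reps`
#' datasets (each from a deterministic per-replicate seed), runs the method,
#' and evaluates AUC and precision/sensitivity/F-score at the method's
#' default cutoff. Genes dropped as all-zero are scored against the truth of
#' the retained genes.
#'
#' @param methods Character subset of `c("lfcseq", "noiseq-like", "shgt")`.
#' @param sample_sizes List of `c(n_A, n_B)` pairs.
#' @param n_reps Replicates per cell.
#' @param base_seed Base seed from which all per-replicate seeds derive.
#' @param params Template [sim_params()]; `n_A`, `n_B` and `seed` are
#'   overridden per cell.
#' @param param_table Optional empirical parameter table; when supplied,
#'   datasets come from [simulate_sim2()] instead of [simulate_sim1()].
#' @param k Neighborhood size passed to the LFCseq run.
#' @return List with `summary` (per method x sample size: mean/sd AUC, mean
#'   PRE/SEN/FS) and `reps` (the full per-replicate table).
#' @export
run_bench <- function(methods = c("lfcseq", "noiseq-like"),
                      sample_sizes = list(c(2L, 2L), c(5L, 5L), c(8L, 8L)),
                      n_reps = 5L, base_seed = 1L,
                      params = sim_params(), param_table = NULL, k = 50L) {
  stopifnot(n_reps >= 1L)
  methods <- match.arg(methods, c("lfcseq", "noiseq-like", "shgt"),
                       several.ok = TRUE)
  rows <- list()
  for (s in seq_along(sample_sizes)) {
    sz <- sample_sizes[[s]]
    for (r in seq_len(n_reps)) {
      seed_r <- bench_seed(base_seed, s, r)
      p <- params
      p$n_A <- as.integer(sz[1L])
      p$n_B <- as.integer(sz[2L])
      p$seed <- seed_r
      sim <- if (is.null(param_table)) {
        simulate_sim1(p)
      } else {
        simulate_sim2(param_table, p)
      }
      kept <- rowSums(sim$counts) > 0
      truth <- sim$truth[kept]
      for (m in methods) {
        out <- run_method(m, sim, k = k, seed = seed_r)
        ev <- evaluate_results(out$scores, out$calls, truth)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, n_A = sz[1L], n_B = sz[2L], rep = r, seed = seed_r,
          auc = ev$auc, pre = ev$pre, sen = ev$sen, fs = ev$fs,
          stringsAsFactors = FALSE)
      }
    }
  }
  reps <- do.call(rbind, rows)
  agg <- function(df) {
    data.frame(method = df$method[1L], n_A = df$n_A[1L], n_B = df$n_B[1L],
               n_reps = nrow(df),
               mean_auc = mean(df$auc), sd_auc = stats::sd(df$auc),
               mean_pre = mean(df$pre, na.rm = TRUE),
               mean_sen = mean(df$sen, na.rm = TRUE),
               mean_fs = mean(df$fs, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }
  cell <- interaction(reps$method, reps$n_A, reps$n_B, drop = TRUE)
  summary <- do.call(rbind, lapply(split(reps, cell), agg))
  summary <- summary[order(summary$n_A, summary$n_B, summary$method), ]
  rownames(summary) <- NULL
  list(summary = summary, reps = reps)
}
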