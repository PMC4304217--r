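#' Negative binomial draws parameterized by mean and dispersion
#'
#' Draws counts with \eqn{E[N] = \mu} and \eqn{Var[N] = \mu + \phi \mu^2}
#' (the usual RNA-seq mean-variance form; `size = 1/phi`). `phi = 0` is the
#' Poisson limit.
#'
#' @param n Number of draws.
#' @param mu Positive mean(s), recycled to length `n`.
#' @param phi Non-negative dispersion(s), recycled to length `n`.
#' @return Integer-valued numeric vector of counts.
#' @export
nb_draw <- function(n, mu, phi) {
  mu <- rep_len(mu, n)
  phi <- rep_len(phi, n)
  if (any(mu <= 0)) stop("mu must be strictly positive")
  if (any(phi < 0)) stop("phi must be non-negative")
  out <- numeric(n)
  pois <- phi == 0
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    out[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                 size = 1 / phi[!pois])
  }
  out
}

#' Default simulation parameters
#'
#' The generator emulates a two-condition RNA-seq experiment: negative
#' binomial counts with \eqn{\mu_{ij} = q_i d_j} and
#' \eqn{\sigma^2_{ij} = \mu_{ij} + \phi_i \mu_{ij}^2}, 30\% of genes
#' differentially expressed of which 70\% up-regulated, and library size
#' factors \eqn{d_j \sim U(0.5, 1.5)}. Baseline expression, fold change and
#' dispersion laws default to a log-normal baseline
#' \eqn{q_{iA} \sim \mathrm{LogNormal}(\log 200, 1)}, multiplicative DE fold
#' changes \eqn{\sim U(1.5, 4)}, and dispersions
#' \eqn{\phi_i \sim U(0.05, 0.5)}.
#'
#' @param n_genes Number of genes.
#' @param prop_DE Fraction of DE genes (exact count, rounded).
#' @param prop_up Fraction of DE genes that are up-regulated in condition B
#'   (exact count, rounded).
#' @param n_A,n_B Samples per condition.
#' @param depth_low,depth_high Range of the uniform library-size factors.
#' @param baseline_law Function `n -> positive q_iA` values.
#' @param fold_law Function `n -> fold changes > 1` for DE genes.
#' @param dispersion_law Function `n -> non-negative phi_i` values.
#' @param seed Integer seed; the whole dataset is a pure function of it.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(n_genes = 20000L, prop_DE = 0.3, prop_up = 0.7,
                       n_A = 5L, n_B = 5L,
                       depth_low = 0.5, depth_high = 1.5,
                       baseline_law = function(n) stats::rlnorm(n, log(200), 1),
                       fold_law = function(n) stats::runif(n, 1.5, 4),
                       dispersion_law = function(n) stats::runif(n, 0.05, 0.5),
                       seed = 1L) {
  stopifnot(prop_DE >= 0, prop_DE <= 1, prop_up >= 0, prop_up <= 1,
            depth_low < depth_high, depth_low > 0,
            n_genes >= 1, n_A >= 1, n_B >= 1)
  structure(list(n_genes = as.integer(n_genes), prop_DE = prop_DE,
                 prop_up = prop_up, n_A = as.integer(n_A),
                 n_B = as.integer(n_B), depth_low = depth_low,
                 depth_high = depth_high, baseline_law = baseline_law,
                 fold_law = fold_law, dispersion_law = dispersion_law,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Shared count-generation backbone: given per-gene (q_A, q_B, phi) and
# params, draw depths and NB counts, assemble matrix + design + truth.
simulate_counts <- function(qA, qB, phi, truth, direction, p) {
  G <- p$n_genes
  n <- p$n_A + p$n_B
  d <- stats::runif(n, p$depth_low, p$depth_high)
  q <- cbind(matrix(rep(qA, p$n_A), ncol = p$n_A),
             matrix(rep(qB, p$n_B), ncol = p$n_B))
  mu <- sweep(q, 2L, d, "*")
  counts <- matrix(nb_draw(G * n, mu = as.vector(mu),
                           phi = rep(phi, times = n)),
                   nrow = G, ncol = n)
  gene_ids <- sprintf("g%0*d", nchar(G), seq_len(G))
  sample_ids <- c(sprintf("A%d", seq_len(p$n_A)),
                  sprintf("B%d", seq_len(p$n_B)))
  dimnames(counts) <- list(gene_ids, sample_ids)
  design <- stats::setNames(rep(c("A", "B"), c(p$n_A, p$n_B)), sample_ids)
  structure(list(counts = counts, design = design,
                 truth = stats::setNames(truth, gene_ids),
                 direction = stats::setNames(direction, gene_ids),
                 q_A = stats::setNames(qA, gene_ids),
                 q_B = stats::setNames(qB, gene_ids),
                 phi = stats::setNames(phi, gene_ids),
                 depth = stats::setNames(d, sample_ids),
                 params = p),
            class = "sim_dataset")
}

#' Simulate a two-condition NB dataset with parametric gene effects
#'
#' Draws per-gene baseline expressions from `baseline_law`, marks an exact
#' `round(prop_DE * n_genes)` genes as DE (of which an exact
#' `round(prop_up * n_DE)` are up-regulated in condition B), applies
#' multiplicative fold changes from `fold_law` to the DE genes, draws
#' per-sample library factors, and generates NB counts with
#' \eqn{\mu_{ij} = q_i d_j} and \eqn{\sigma^2 = \mu + \phi_i \mu^2}.
#'
#' @param p Parameters from [sim_params()].
#' @return A `sim_dataset` list: `counts`, `design`, `truth` (0/1 per gene),
#'   `direction` ("up"/"down"/"none"), the generating `q_A`, `q_B`, `phi`,
#'   `depth`, and the `params` echo.
#' @export
simulate_sim1 <- function(p = sim_params()) {
  stopifnot(inherits(p, "sim_params"))
  with_seed(p$seed, {
    G <- p$n_genes
    qA <- p$baseline_law(G)
    if (any(qA <= 0)) stop("baseline law produced non-positive expression")
    n_de <- round(p$prop_DE * G)
    n_up <- round(p$prop_up * n_de)
    de_idx <- sample.int(G, n_de)
    up_idx <- if (n_de > 0) de_idx[seq_len(n_up)] else integer(0)
    down_idx <- setdiff(de_idx, up_idx)
    truth <- integer(G)
    truth[de_idx] <- 1L
    direction <- rep("none", G)
    direction[up_idx] <- "up"
    direction[down_idx] <- "down"
    fold <- p$fold_law(n_de)
    if (any(fold <= 0)) stop("fold law produced non-positive fold changes")
    qB <- qA
    qB[up_idx] <- qA[up_idx] * fold[match(up_idx, de_idx)]
    qB[down_idx] <- qA[down_idx] / fold[match(down_idx, de_idx)]
    phi <- p$dispersion_law(G)
    if (any(phi < 0)) stop("dispersion law produced negative values")
    simulate_counts(qA, qB, phi, truth, direction, p)
  })
}

#' Simulate a dataset by resampling empirical per-gene parameters
#'
#' Like [simulate_sim1()] but the per-gene triples \eqn{(q_{iA}, q_{iB},
#' \phi_i)} are drawn jointly (rows kept intact) with replacement from an
#' empirical parameter table, e.g. one estimated from a real two-condition
#' experiment. Ground truth is \eqn{x_i = [q_{iA} \neq q_{iB}]} unless the
#' table carries an explicit `de` column.
#'
#' @param param_table Data frame with numeric columns `qA`, `qB`, `phi`
#'   (optionally a 0/1 `de` column), one row per source gene.
#' @param p Parameters from [sim_params()]; the expression/fold/dispersion
#'   laws are ignored.
#' @return A `sim_dataset` list as in [simulate_sim1()].
#' @export
simulate_sim2 <- function(param_table, p = sim_params()) {
  stopifnot(inherits(p, "sim_params"))
  req <- c("qA", "qB", "phi")
  if (!all(req %in% names(param_table))) {
    stop("parameter table must have columns qA, qB, phi")
  }
  if (nrow(param_table) == 0L) stop("parameter table is empty")
  if (any(param_table$qA <= 0) || any(param_table$qB <= 0)) {
    stop("expression parameters qA, qB must be strictly positive")
  }
  if (any(param_table$phi < 0)) stop("dispersion phi must be non-negative")
  with_seed(p$seed, {
    G <- p$n_genes
    rows <- sample.int(nrow(param_table), G, replace = TRUE)
    qA <- param_table$qA[rows]
    qB <- param_table$qB[rows]
    phi <- param_table$phi[rows]
    truth <- if ("de" %in% names(param_table)) {
      as.integer(param_table$de[rows])
    } else {
      as.integer(qA != qB)
    }
    direction <- ifelse(truth == 0L, "none", ifelse(qB > qA, "up", "down"))
    simulate_counts(qA, qB, phi, truth, direction, p)
  })
}

#' Read a per-gene (qA, qB, phi) parameter table from TSV
#'
#' @param path TSV with header columns `qA`, `qB`, `phi` (extra columns are
#'   kept).
#' @return Data frame suitable for [simulate_sim2()].
#' @export
read_param_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t")
  req <- c("qA", "qB", "phi")
  if (!all(req %in% names(tab))) {
    stop("parameter table must have columns qA, qB, phi")
  }
  tab
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `<prefix>_counts.tsv`, `<prefix>_design.tsv` and
#' `<prefix>_truth.tsv` (gene_id, de, direction).
#'
#' @param sim A `sim_dataset`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three paths.
#' @export
write_sim <- function(sim, prefix) {
  stopifnot(inherits(sim, "sim_dataset"))
  cpath <- paste0(prefix, "_counts.tsv")
  dpath <- paste0(prefix, "_design.tsv")
  tpath <- paste0(prefix, "_truth.tsv")
  cnt <- data.frame(gene_id = rownames(sim$counts), sim$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cnt, cpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(sim$design),
                                condition = unname(sim$design)),
                     dpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = names(sim$truth),
                                de = unname(sim$truth),
                                direction = unname(sim$direction)),
                     tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts = cpath, design = dpath, truth = tpath))
}
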