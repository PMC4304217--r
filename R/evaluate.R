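#' Area under the ROC curve of a DE-evidence ranking
#'
#' Rank-based AUC with midrank tie handling: equals the probability that a
#' randomly chosen truly DE gene scores higher than a randomly chosen
#' non-DE gene (ties count one half). For LFCseq-style output use
#' `1 - prob_nonDE` as the score.
#'
#' @param scores Per-gene DE-evidence scores (larger = more evidence).
#' @param truth Per-gene 0/1 ground truth.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.integer(truth)
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC needs both DE and non-DE genes in the truth")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @inheritParams auc_score
#' @return Data frame of (FPR, TPR) points along decreasing score cutoffs.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.integer(truth)
  ord <- order(-scores, seq_along(scores))
  tp <- cumsum(truth[ord] == 1L)
  fp <- cumsum(truth[ord] == 0L)
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  data.frame(FPR = c(0, fp / n_neg), TPR = c(0, tp / n_pos))
}

#' False-discovery-rate curve along a ranking
#'
#' For each k, the fraction of false positives among the top-k ranked genes.
#' Ties in the score keep their input order (stable ranking).
#'
#' @param scores Per-gene DE-evidence scores (larger = more evidence), or
#'   `NULL` if `ranking` is given.
#' @param truth Per-gene 0/1 ground truth.
#' @param ranking Optional explicit gene ordering (indices, most significant
#'   first); overrides `scores`.
#' @return Data frame with columns `n_called` (1..G) and `FDR`.
#' @export
fdr_curve <- function(scores, truth, ranking = NULL) {
  truth <- as.integer(truth)
  if (is.null(ranking)) {
    ranking <- order(-scores, seq_along(scores))
  }
  fp <- cumsum(truth[ranking] == 0L)
  k <- seq_along(ranking)
  data.frame(n_called = k, FDR = fp / k)
}

#' Precision, sensitivity and F-score of binary DE calls
#'
#' PRE = TP/(TP+FP), SEN = TP/(TP+FN), FS = 2*PRE*SEN/(PRE+SEN). A zero
#' denominator yields `NA` for the affected metric (e.g. no genes called
#' gives PRE = NA and hence FS = NA); FS is also `NA` when PRE and SEN are
#' both zero.
#'
#' @param calls Per-gene 0/1 DE calls.
#' @param truth Per-gene 0/1 ground truth.
#' @return List with `pre`, `sen`, `fs`, and the counts `tp`, `fp`, `fn`.
#' @export
prf <- function(calls, truth) {
  calls <- as.integer(calls)
  truth <- as.integer(truth)
  stopifnot(length(calls) == length(truth))
  tp <- sum(calls == 1L & truth == 1L)
  fp <- sum(calls == 1L & truth == 0L)
  fn <- sum(calls == 0L & truth == 1L)
  pre <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  sen <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  fs <- if (is.na(pre) || is.na(sen) || (pre == 0 && sen == 0)) {
    NA_real_
  } else {
    2 * pre * sen / (pre + sen)
  }
  list(pre = pre, sen = sen, fs = fs, tp = tp, fp = fp, fn = fn)
}

#' Full evaluation report for one method's output against ground truth
#'
#' @param scores Per-gene DE-evidence scores (larger = more evidence).
#' @param calls Per-gene 0/1 DE calls at the method's default cutoff.
#' @param truth Per-gene 0/1 ground truth.
#' @return List with `auc`, `roc`, `fdr_curve`, and the [prf()] fields.
#' @export
evaluate_results <- function(scores, calls, truth) {
  c(list(auc = auc_score(scores, truth),
         roc = roc_curve(scores, truth),
         fdr_curve = fdr_curve(scores, truth)),
    prf(calls, truth))
}
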