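#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a tab-separated file whose first row holds sample identifiers and
#' whose first column holds gene identifiers; the body must be numeric and
#' non-negative. Row and column order are preserved exactly as found in the
#' file.
#'
#' @param path Path to a UTF-8 TSV file with header
#'   \code{gene_id<TAB>sample1<TAB>...}.
#' @return An integer-valued numeric matrix with \code{rownames} = gene ids
#'   and \code{colnames} = sample ids.
#' @export
read_counts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) {
    stop("count file must contain a header line and at least one gene row")
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop("count file header must name at least one sample")
  }
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1L]
    stop("duplicate sample ID in header: '", dup, "'")
  }
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ncol_expect <- length(header)
  gene_ids <- character(length(body))
  counts <- matrix(0, nrow = length(body), ncol = length(sample_ids))
  for (r in seq_along(body)) {
    row <- body[[r]]
    if (length(row) != ncol_expect) {
      stop("row ", r + 1L, ": expected ", ncol_expect, " fields, found ",
           length(row))
    }
    gene_ids[r] <- row[1L]
    vals <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1L]
      stop("row ", r + 1L, ", column ", bad + 1L, ": non-numeric count '",
           row[bad + 1L], "'")
    }
    if (any(vals < 0)) {
      bad <- which(vals < 0)[1L]
      stop("row ", r + 1L, ", column ", bad + 1L, ": negative count ",
           vals[bad])
    }
    counts[r, ] <- vals
  }
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1L]
    stop("duplicate gene ID: '", dup, "'")
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  counts
}

#' Read a two-condition design table from TSV
#'
#' The file must have a header \code{sample_id<TAB>condition} and exactly two
#' distinct condition labels, each with at least one sample.
#'
#' @param path Path to the design TSV.
#' @return A named character vector mapping sample id to condition label, in
#'   file order.
#' @export
read_design <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) != 2L) {
    stop("design file must have exactly two columns (sample_id, condition)")
  }
  samples <- tab[[1L]]
  cond <- tab[[2L]]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ID in design: '",
         samples[duplicated(samples)][1L], "'")
  }
  labels <- unique(cond)
  if (length(labels) != 2L) {
    stop("design must contain exactly two distinct condition labels, found ",
         length(labels))
  }
  if (any(tabulate(factor(cond, levels = labels)) == 0L)) {
    stop("both conditions must contain at least one sample")
  }
  stats::setNames(cond, samples)
}

#' Split the samples of a count matrix by condition
#'
#' Joins a design vector against the matrix columns and returns the column
#' indices of each condition. Every matrix sample must be present in the
#' design.
#'
#' @param counts Count matrix (samples in columns).
#' @param design Named condition vector as returned by [read_design()].
#' @return A list of two integer vectors of column indices, named by the two
#'   condition labels (in order of first appearance in `design`).
#' @export
condition_groups <- function(counts, design) {
  samples <- colnames(counts)
  missing <- setdiff(samples, names(design))
  if (length(missing) > 0L) {
    stop("sample '", missing[1L], "' in count matrix has no condition label")
  }
  cond <- design[samples]
  labels <- unique(design)[unique(design) %in% cond]
  if (length(labels) != 2L) {
    stop("count matrix samples must cover both conditions")
  }
  groups <- lapply(labels, function(l) unname(which(cond == l)))
  names(groups) <- labels
  groups
}

#' Remove genes with zero counts in every sample
#'
#' Genes whose counts are zero across all samples carry no usable fold-change
#' information and are removed before depth estimation. Removal is reported
#' via a message; the relative order of retained genes is unchanged.
#'
#' @param counts Count matrix.
#' @return The count matrix restricted to genes with at least one positive
#'   count.
#' @export
drop_allzero_genes <- function(counts) {
  keep <- rowSums(counts) > 0
  if (!any(keep)) {
    stop("all genes have zero counts in every sample; nothing to analyse")
  }
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message("removed ", n_drop, " all-zero gene(s): ",
            paste(utils::head(rownames(counts)[!keep], 5L), collapse = ", "),
            if (n_drop > 5L) ", ..." else "")
  }
  counts[keep, , drop = FALSE]
}

#' Replace zero counts by 0.5 on the normalized scale
#'
#' Cells whose raw count was zero are set to 0.5 in the normalized matrix so
#' that log fold changes are always defined; all other cells are untouched.
#' The replacement is keyed on the raw matrix, not on the normalized values.
#'
#' @param normalized Normalized count matrix (same shape as `raw`).
#' @param raw Raw count matrix used to locate zero cells.
#' @return The normalized matrix with former zero cells set to 0.5.
#' @export
replace_zeros <- function(normalized, raw) {
  stopifnot(identical(dim(normalized), dim(raw)))
  normalized[raw == 0] <- 0.5
  normalized
}

#' Write a differential-expression result table to TSV
#'
#' Columns are \code{gene_id}, \code{mean_A}, \code{mean_B}, \code{log2FC},
#' \code{prob_nonDE} and \code{de_call}; numeric columns are written with six
#' significant digits and genes keep their input order.
#'
#' @param results Data frame as returned by [run_lfcseq()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  out <- results
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], function(x) trimws(formatC(signif(x, 6L),
                                                          format = "g",
                                                          digits = 6L)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
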