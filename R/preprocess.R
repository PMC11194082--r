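#' Remove high-mitochondrial cells and mitochondrial genes
#'
#' Cells whose mitochondrial expression fraction (summed expression of flagged
#' genes divided by total expression) is strictly greater than `max_fraction`
#' are removed, and all flagged genes are dropped from the result. Which genes
#' are mitochondrial is decided by the caller (species-specific naming such as
#' the "MT-" prefix is resolved upstream), either as a logical vector aligned
#' with the columns or as a character vector of gene ids.
#'
#' @param m Cells x genes matrix.
#' @param mito_genes Logical vector (one flag per gene) or character vector of
#'   mitochondrial gene ids.
#' @param max_fraction Maximum tolerated mitochondrial fraction, in \[0, 1\].
#'   Default 0.15.
#' @return Filtered matrix.
#' @export
#' @examples
#' m <- toy_bipartite_fixture()
#' filter_mito(m, mito_genes = rep(FALSE, ncol(m)))  # no-op
filter_mito <- function(m, mito_genes, max_fraction = 0.15) {
  m <- as_expression_matrix(m)
  if (is.character(mito_genes)) {
    missing <- setdiff(mito_genes, colnames(m))
    if (length(missing)) stop("mito gene ids not in matrix: ", paste(missing, collapse = ", "),
                              call. = FALSE)
    mito_genes <- colnames(m) %in% mito_genes
  }
  if (!is.logical(mito_genes) || length(mito_genes) != ncol(m)) {
    stop("`mito_genes` must be a logical flag per gene (length ", ncol(m), ")", call. = FALSE)
  }
  if (!is.numeric(max_fraction) || max_fraction < 0 || max_fraction > 1) {
    stop("`max_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (!any(mito_genes)) return(m)
  tot <- row_sums(m)
  mito <- if (sum(mito_genes) == 1L) as.numeric(m[, mito_genes]) else row_sums(m[, mito_genes, drop = FALSE])
  frac <- ifelse(tot > 0, mito / tot, 0)
  keep_cells <- frac <= max_fraction   # strictly "more than" is removed
  if (!any(keep_cells)) stop("all cells exceed the mitochondrial fraction threshold", call. = FALSE)
  m[keep_cells, !mito_genes, drop = FALSE]
}

#' Drop all-zero cells and genes
#'
#' Removes cells with no expression and genes not expressed in any cell.
#' A single pass over rows then columns reaches a fixed point: removing a
#' zero column cannot create a new zero row among rows that had positive
#' entries elsewhere only in that column, because a zero column has no
#' positive entries. The operation is therefore idempotent.
#'
#' @param m Cells x genes matrix.
#' @return Matrix with no all-zero rows or columns.
#' @export
filter_empty <- function(m) {
  m <- as_expression_matrix(m)
  keep_c <- row_sums(m) > 0
  keep_g <- col_sums(m) > 0
  if (!any(keep_c) || !any(keep_g)) stop("filtering removed everything: matrix is all zero",
                                         call. = FALSE)
  m[keep_c, keep_g, drop = FALSE]
}

#' Library-size normalization followed by log(1 + x)
#'
#' Each cell's counts are scaled so that its total equals `target_sum` (or the
#' median of the pre-normalization per-cell totals when `target_sum =
#' "median"`), then every entry x is replaced by log(1 + x) in the requested
#' base. Zeros stay exactly zero, so the support pattern is preserved; both
#' steps are strictly monotone per cell, so rank-based downstream statistics
#' are unchanged by the choice of base.
#'
#' @param m Cells x genes matrix with no all-zero cells.
#' @param target_sum Positive number, or `"median"` (default).
#' @param base Logarithm base; 2 by default, `exp(1)` for the natural log.
#' @param log_transform Set to `FALSE` to stop after rescaling.
#' @return Normalized matrix.
#' @export
normalize_log <- function(m, target_sum = "median", base = 2, log_transform = TRUE) {
  m <- as_expression_matrix(m)
  tot <- row_sums(m)
  if (any(tot == 0)) stop("matrix has all-zero cells; run filter_empty() first", call. = FALSE)
  if (identical(target_sum, "median")) {
    target_sum <- stats::median(tot)
  } else if (!is.numeric(target_sum) || length(target_sum) != 1L || target_sum <= 0) {
    stop("`target_sum` must be a positive number or \"median\"", call. = FALSE)
  }
  if (inherits(m, "Matrix")) {
    out <- Matrix::Diagonal(x = target_sum / tot) %*% m
    dimnames(out) <- dimnames(m)
  } else {
    # length-nrow vector recycles down columns: per-cell scaling
    out <- m * (target_sum / tot)
  }
  if (log_transform) out <- log1p(out) / log(base)
  out
}

#' Binarize an expression matrix
#'
#' Maps entries strictly above `threshold` to 1 and the rest to 0. With the
#' default threshold this turns weighted diversity/ubiquity (sums of
#' expression) into expressed-gene and expressing-cell counts.
#'
#' @param m Cells x genes matrix.
#' @param threshold Entries > `threshold` become 1. Default 0.
#' @return Binary matrix of the same shape and dimnames.
#' @export
binarize <- function(m, threshold = 0) {
  m <- as_expression_matrix(m)
  out <- (m > threshold) * 1
  dimnames(out) <- dimnames(m)
  out
}
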