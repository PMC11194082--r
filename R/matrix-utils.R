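# Internal helpers shared across modules. The package-wide convention is a
# cells x genes non-negative matrix (base matrix or Matrix sparse class) with
# cell ids as rownames and gene ids as colnames.

row_sums <- function(m) as.numeric(Matrix::rowSums(m))
col_sums <- function(m) as.numeric(Matrix::colSums(m))

#' Validate a cells-by-genes expression matrix
#'
#' Checks the container contract used throughout the package: a numeric base
#' matrix or a `Matrix` sparse matrix, no negative entries, unique cell and
#' gene ids. Missing dimnames are filled in with `cell_<i>` / `gene_<j>`.
#'
#' @param m A cells x genes matrix (base or `Matrix`).
#' @param require_nonempty_margins If `TRUE`, additionally require that no
#'   cell (row) and no gene (column) is all-zero, i.e. the matrix has already
#'   been through [filter_empty()].
#' @return The validated matrix, with dimnames guaranteed.
#' @export
as_expression_matrix <- function(m, require_nonempty_margins = FALSE) {
  if (!(is.matrix(m) && is.numeric(m)) && !inherits(m, "Matrix")) {
    stop("`m` must be a numeric matrix or a Matrix sparse matrix", call. = FALSE)
  }
  if (nrow(m) == 0L || ncol(m) == 0L) {
    stop("expression matrix is empty (", nrow(m), " cells x ", ncol(m), " genes)",
         call. = FALSE)
  }
  if (min(m) < 0) stop("expression matrix has negative entries", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("cell_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("gene_", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate cell ids", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate gene ids", call. = FALSE)
  if (require_nonempty_margins) {
    if (any(row_sums(m) == 0)) stop("matrix has all-zero cells; run filter_empty() first",
                                    call. = FALSE)
    if (any(col_sums(m) == 0)) stop("matrix has all-zero genes; run filter_empty() first",
                                    call. = FALSE)
  }
  m
}

# min-max scale a vector to [0, 1]; constant vectors go to all-zero with a
# warning when warn_constant, since the index is undefined there.
minmax <- function(x, warn_constant = TRUE, what = "vector") {
  r <- range(x)
  # constant up to float noise: a range this small carries no ranking signal
  if (diff(r) <= 1e-12 * max(abs(r[1]), abs(r[2]), 1)) {
    if (warn_constant) warning(what, " is constant; min-max normalization is degenerate, returning zeros",
                               call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

# Spearman correlation without the cor() surprises for constant input
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch in correlation", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

# Map stage labels to integer codes 0..K-1 in declared (or factor/sorted) order.
stage_codes <- function(stages, stage_order = NULL) {
  if (is.null(stage_order)) {
    stage_order <- if (is.factor(stages)) levels(stages) else sort(unique(as.character(stages)))
  }
  stages <- as.character(stages)
  if (!all(stages %in% stage_order)) {
    stop("stage labels not covered by `stage_order`: ",
         paste(setdiff(stages, stage_order), collapse = ", "), call. = FALSE)
  }
  match(stages, stage_order) - 1L
}
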