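#' Cell diversity (0th-order cell complexity)
#'
#' The diversity of a cell is the sum of its expression over all genes: the
#' weighted degree of the cell node in the cell-gene bipartite network. On a
#' binarized matrix this is the number of expressed genes.
#'
#' @param m Cells x genes matrix with no all-zero cells.
#' @return Named numeric vector, one entry per cell, strictly positive.
#' @seealso [gene_ubiquity()], [binarize()]
#' @export
cell_diversity <- function(m) {
  m <- as_expression_matrix(m)
  k <- row_sums(m)
  if (any(k == 0)) stop("zero-diversity cell present; run filter_empty() first", call. = FALSE)
  stats::setNames(k, rownames(m))
}

#' Gene ubiquity (0th-order gene complexity)
#'
#' The ubiquity of a gene is the sum of its expression over all cells: the
#' weighted degree of the gene node. On a binarized matrix this is the number
#' of cells expressing the gene.
#'
#' @param m Cells x genes matrix with no all-zero genes.
#' @return Named numeric vector, one entry per gene, strictly positive.
#' @export
gene_ubiquity <- function(m) {
  m <- as_expression_matrix(m)
  k <- col_sums(m)
  if (any(k == 0)) stop("zero-ubiquity gene present; run filter_empty() first", call. = FALSE)
  stats::setNames(k, colnames(m))
}

#' Multi-order complexity by the method of reflections
#'
#' Starting from diversity and ubiquity, cell complexity at order N is the
#' expression-weighted average of gene complexity at order N-1 (divided by the
#' cell's 0th-order diversity), and symmetrically for genes. The recursion is
#' run on raw values; reported columns are additionally min-max scaled to
#' \[0, 1\] when `normalize = TRUE`, with the raw columns retained in the
#' result (normalizing inside the recursion would change its fixed points).
#'
#' @param m Cells x genes matrix with no all-zero rows or columns.
#' @param n_max Highest order to compute (>= 0).
#' @param normalize Min-max scale each reported column. Default `TRUE`.
#' @return An object of class `sctc_reflections`: a list with cell and gene
#'   complexity matrices (`cell`, `gene`, columns named `k0` ... `k<n_max>`),
#'   their raw counterparts (`cell_raw`, `gene_raw`), `n_max` and `normalized`.
#' @export
#' @examples
#' r <- reflections(toy_bipartite_fixture(), n_max = 4)
#' tidy(r)
reflections <- function(m, n_max, normalize = TRUE) {
  m <- as_expression_matrix(m, require_nonempty_margins = TRUE)
  if (!is.numeric(n_max) || length(n_max) != 1L || n_max < 0 || n_max != floor(n_max)) {
    stop("`n_max` must be a non-negative integer", call. = FALSE)
  }
  n_max <- as.integer(n_max)
  kc0 <- row_sums(m)
  kg0 <- col_sums(m)
  kc <- matrix(NA_real_, nrow(m), n_max + 1L,
               dimnames = list(rownames(m), paste0("k", 0:n_max)))
  kg <- matrix(NA_real_, ncol(m), n_max + 1L,
               dimnames = list(colnames(m), paste0("k", 0:n_max)))
  kc[, 1L] <- kc0
  kg[, 1L] <- kg0
  if (n_max >= 1L) {
    for (N in seq_len(n_max)) {
      kc[, N + 1L] <- as.numeric(m %*% kg[, N]) / kc0
      kg[, N + 1L] <- as.numeric(Matrix::crossprod(m, kc[, N])) / kg0
    }
  }
  out <- list(
    cell = if (normalize) apply(kc, 2L, minmax, warn_constant = FALSE) else kc,
    gene = if (normalize) apply(kg, 2L, minmax, warn_constant = FALSE) else kg,
    cell_raw = kc,
    gene_raw = kg,
    n_max = n_max,
    normalized = normalize
  )
  # apply() drops dimnames rownames? it keeps them; make sure of names anyway
  dimnames(out$cell) <- dimnames(kc)
  dimnames(out$gene) <- dimnames(kg)
  class(out) <- "sctc_reflections"
  out
}

#' Cell-cell similarity matrix of the two-step reflection
#'
#' Collapsing two reflection steps gives a linear map on cell complexities:
#' entry (c, c') sums over genes the product of the two cells' expression,
#' scaled by cell c's diversity and each gene's ubiquity. The result is
#' row-stochastic (every row sums to exactly 1), non-negative, and has the
#' constant vector as eigenvector for its leading eigenvalue 1; the second
#' eigenvector carries the complexity signal.
#'
#' @param m Cells x genes matrix with no all-zero rows or columns.
#' @return Dense cells x cells base matrix with cell ids as dimnames and
#'   attribute `source_dims = c(cells, genes)`.
#' @export
cell_cell_matrix <- function(m) {
  m <- as_expression_matrix(m, require_nonempty_margins = TRUE)
  kc0 <- row_sums(m)
  kg0 <- col_sums(m)
  if (inherits(m, "Matrix")) {
    a <- Matrix::Diagonal(x = 1 / kc0) %*% m %*% Matrix::Diagonal(x = 1 / kg0)
    mt <- as.matrix(Matrix::tcrossprod(a, m))
  } else {
    mt <- (m / kc0) %*% (t(m) / kg0)
  }
  dimnames(mt) <- list(rownames(m), rownames(m))
  attr(mt, "source_dims") <- dim(m)
  mt
}

# Number of connected components of the cell-gene bipartite support graph.
bipartite_components <- function(m) {
  supp <- Matrix::Matrix(m != 0, sparse = TRUE)
  g <- igraph::graph_from_biadjacency_matrix(supp)
  igraph::components(g)$no
}

#' Analytic cell and gene complexity indices (CCI / GCI)
#'
#' The even-order reflections recursion converges, up to normalization, to
#' the eigenvector of the cell-cell matrix associated with its second-largest
#' eigenvalue. This function computes that eigenvector analytically, orients
#' it so that its Spearman correlation with cell diversity is positive (an
#' eigenvector's sign is arbitrary; diversity is the weakly informative
#' anchor), min-max scales it to \[0, 1\] as the Cell Complexity Index, and,
#' when `compute_gci = TRUE`, derives the Gene Complexity Index as the
#' normalized expression-weighted average of CCI over each gene's expressing
#' cells. Pseudotime is 1 - CCI.
#'
#' The spectrum is computed on the symmetric similar matrix
#' S = D^{-1/2} M Dg^{-1} M' D^{-1/2} (D, Dg diagonal diversity/ubiquity), so
#' eigenvalues are real and non-negative and the computation is deterministic.
#'
#' @param m Cells x genes matrix with no all-zero rows or columns.
#' @param compute_gci Also populate GCI. Default `TRUE`.
#' @param degeneracy_tol Minimum admissible gap between the second and third
#'   eigenvalues before the second eigenvector is declared non-unique.
#' @return An object of class `sctc_complexity`: list with tibbles `cells`
#'   (cell, diversity, cci, pseudotime) and `genes` (gene, ubiquity, gci),
#'   plus `second_eigenvalue`, `sign_scc` (the positive Spearman correlation
#'   of the chosen orientation with diversity), `K_raw`, `Q_raw`.
#' @export
#' @examples
#' sim <- generate_trajectory(trajectory_config(seed = 1))
#' idx <- sctc_cci(sim$matrix)
#' glance(idx)
sctc_cci <- function(m, compute_gci = TRUE, degeneracy_tol = 1e-10) {
  m <- as_expression_matrix(m, require_nonempty_margins = TRUE)
  if (bipartite_components(m) > 1L) {
    stop("the cell-gene bipartite network is disconnected; the second eigenvector ",
         "would encode component membership, not development. Analyse components separately.",
         call. = FALSE)
  }
  if (nrow(m) > 50000L) {
    warning("building a dense ", nrow(m), " x ", nrow(m),
            " cell-cell matrix; expect heavy memory use", call. = FALSE)
  }
  kc0 <- row_sums(m)
  kg0 <- col_sums(m)
  # symmetric similar matrix: S = D^{-1/2} M Dg^{-1} M' D^{-1/2} = B B'
  b <- as.matrix(m) / sqrt(kc0)
  b <- t(t(b) / sqrt(kg0))
  s <- tcrossprod(b)
  es <- eigen(s, symmetric = TRUE)
  lambda <- es$values
  if (length(lambda) < 2L) {
    stop("need at least two cells for a second eigenvector", call. = FALSE)
  }
  gap <- lambda[2] - if (length(lambda) >= 3L) lambda[3] else -Inf
  if (is.finite(gap) && gap < degeneracy_tol) {
    stop("second eigenvalue is degenerate (gap ", format(gap), " < ", degeneracy_tol,
         "); complexity orientation is undefined on an eigenspace. ",
         "Perturb the matrix or report non-uniqueness.", call. = FALSE)
  }
  K <- es$vectors[, 2] / sqrt(kc0)   # map back through the similarity transform
  if (diff(range(K)) < 1e-12) {
    stop("second eigenvector is constant; complexity is degenerate for this matrix",
         call. = FALSE)
  }
  s_scc <- spearman(K, kc0)
  if (is.na(s_scc) || s_scc == 0) {
    stop("orientation is undefined: Spearman correlation between the second ",
         "eigenvector and diversity is exactly zero. Supply stage labels and pick ",
         "the orientation manually, or inspect the matrix for pathologies.", call. = FALSE)
  }
  if (s_scc < 0) {
    K <- -K
    s_scc <- -s_scc
  }
  cci <- minmax(K, warn_constant = FALSE)
  cells <- tibble::tibble(
    cell = rownames(m),
    diversity = kc0,
    cci = cci,
    pseudotime = 1 - cci
  )
  out <- list(
    cells = cells,
    genes = tibble::tibble(gene = colnames(m), ubiquity = kg0, gci = NA_real_),
    second_eigenvalue = lambda[2],
    eigen_gap = gap,
    sign_scc = s_scc,
    K_raw = stats::setNames(K, rownames(m)),
    Q_raw = NULL,
    transferred = FALSE
  )
  class(out) <- "sctc_complexity"
  if (compute_gci) out <- gci_from_cci(m, out)
  out
}

#' Gene Complexity Index from CCI
#'
#' One reflection step applied to CCI: a gene's raw score Q is the
#' expression-weighted average of CCI over the cells expressing it, divided
#' by the gene's ubiquity; GCI is the min-max normalization of Q.
#'
#' @param m The matrix the indices were computed from.
#' @param indices An `sctc_complexity` object with CCI populated.
#' @return The same object with `genes$gci` and `Q_raw` populated.
#' @export
gci_from_cci <- function(m, indices) {
  stopifnot(inherits(indices, "sctc_complexity"))
  m <- as_expression_matrix(m, require_nonempty_margins = TRUE)
  if (!identical(rownames(m), indices$cells$cell)) {
    stop("matrix cells do not match the indices' cells", call. = FALSE)
  }
  kg0 <- col_sums(m)
  q <- as.numeric(Matrix::crossprod(m, indices$cells$cci)) / kg0
  indices$Q_raw <- stats::setNames(q, colnames(m))
  indices$genes <- tibble::tibble(
    gene = colnames(m),
    ubiquity = kg0,
    gci = minmax(q, what = "Q (raw gene complexity)")
  )
  indices
}

#' Transfer gene complexity across datasets
#'
#' Given an external GCI (computed on another dataset sharing genes with this
#' one), scores each cell by one reflection step over the shared genes: the
#' expression-weighted average of the external gene complexities, normalized
#' by the cell's total expression over shared genes, then min-max scaled to a
#' CCI-like index. This is the cross-dataset transfer protocol: the gene
#' complexity ranking learned on one dataset orders cells of another.
#'
#' @param m Cells x genes matrix.
#' @param external_gci Named numeric vector of gene complexities (names are
#'   gene ids).
#' @return An `sctc_complexity` object (`transferred = TRUE`); `genes$gci`
#'   holds the external values restricted to shared genes.
#' @export
cci_from_external_gci <- function(m, external_gci) {
  m <- as_expression_matrix(m, require_nonempty_margins = TRUE)
  if (is.null(names(external_gci))) stop("`external_gci` must be named by gene id", call. = FALSE)
  shared <- intersect(colnames(m), names(external_gci))
  if (length(shared) == 0L) {
    stop("no genes shared between the matrix (", ncol(m), " genes) and the external GCI (",
         length(external_gci), " genes)", call. = FALSE)
  }
  ms <- m[, shared, drop = FALSE]
  ktot <- row_sums(ms)
  if (any(ktot == 0)) {
    keep <- ktot > 0
    warning(sum(!keep), " cell(s) express no shared gene; dropped from the transfer",
            call. = FALSE)
    ms <- ms[keep, , drop = FALSE]
    ktot <- ktot[keep]
  }
  k <- as.numeric(ms %*% external_gci[shared]) / ktot
  cci <- minmax(k, what = "transferred cell score")
  out <- list(
    cells = tibble::tibble(cell = rownames(ms), diversity = ktot,
                           cci = cci, pseudotime = 1 - cci),
    genes = tibble::tibble(gene = shared, ubiquity = col_sums(ms),
                           gci = unname(external_gci[shared])),
    second_eigenvalue = NA_real_,
    eigen_gap = NA_real_,
    sign_scc = NA_real_,
    K_raw = stats::setNames(k, rownames(ms)),
    Q_raw = NULL,
    transferred = TRUE
  )
  class(out) <- "sctc_complexity"
  out
}

#' Developmental pseudotime from complexity indices
#'
#' Pseudotime is 1 - CCI: high-complexity cells are the least differentiated
#' and sit at the start of the trajectory. Ties keep input order (any ranking
#' applied downstream uses stable ordering).
#'
#' @param indices An `sctc_complexity` object.
#' @return Named numeric vector in \[0, 1\], one entry per cell.
#' @export
pseudotime <- function(indices) {
  stopifnot(inherits(indices, "sctc_complexity"))
  stats::setNames(indices$cells$pseudotime, indices$cells$cell)
}

#' Order at which the reflections recursion collapses
#'
#' The raw recursion converges to a constant vector beyond a threshold order.
#' This reports the smallest even order N at which the relative range
#' (max - min, after dividing the raw cell column by its mean) falls below
#' `tol`, or `NA_integer_` ("not reached") if no computed order qualifies.
#' The relative range is used because the min-max-normalized columns have
#' unit range by construction and cannot express convergence.
#'
#' @param refl An `sctc_reflections` object.
#' @param tol Positive convergence tolerance on the relative range.
#' @return Even integer order, or `NA_integer_` if not reached.
#' @export
convergence_threshold <- function(refl, tol) {
  stopifnot(inherits(refl, "sctc_reflections"))
  if (!is.numeric(tol) || tol < 0) stop("`tol` must be non-negative", call. = FALSE)
  for (N in seq(0L, refl$n_max, by = 2L)) {
    col <- refl$cell_raw[, N + 1L]
    rel_range <- diff(range(col)) / mean(col)
    if (rel_range < tol) return(N)
  }
  NA_integer_
}

#' Select a representative even order by agreement with CCI
#'
#' Returns the even order whose cell-complexity column has the highest
#' Spearman correlation with CCI; ties break toward the smaller order. This
#' is the practical criterion for choosing a finite order N when the
#' recursive route is preferred over the analytic index.
#'
#' @param refl An `sctc_reflections` object.
#' @param indices An `sctc_complexity` object from the same matrix.
#' @return Even integer order.
#' @export
select_order <- function(refl, indices) {
  stopifnot(inherits(refl, "sctc_reflections"), inherits(indices, "sctc_complexity"))
  if (!identical(rownames(refl$cell_raw), indices$cells$cell)) {
    stop("reflections and indices come from different matrices", call. = FALSE)
  }
  orders <- seq(0L, refl$n_max, by = 2L)
  sccs <- vapply(orders, function(N) {
    col <- refl$cell_raw[, N + 1L]
    if (diff(range(col)) == 0) -Inf else spearman(col, indices$cells$cci)
  }, numeric(1))
  orders[which.max(sccs)]  # which.max takes the first maximum: smaller N wins ties
}

#' @export
print.sctc_reflections <- function(x, ...) {
  cat("<sctc_reflections> ", nrow(x$cell), " cells x ", nrow(x$gene), " genes, orders 0..",
      x$n_max, if (x$normalized) " (min-max normalized)" else " (raw)", "\n", sep = "")
  invisible(x)
}

#' @export
print.sctc_complexity <- function(x, ...) {
  cat("<sctc_complexity> ", nrow(x$cells), " cells, ", nrow(x$genes), " genes",
      if (isTRUE(x$transferred)) " (transferred from external GCI)", "\n", sep = "")
  if (!isTRUE(x$transferred)) {
    cat("  second eigenvalue: ", format(x$second_eigenvalue, digits = 4),
        "  orientation SCC vs diversity: ", format(x$sign_scc, digits = 3), "\n", sep = "")
  }
  print(utils::head(x$cells, 5))
  invisible(x)
}
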