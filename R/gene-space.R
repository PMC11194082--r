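#' Revealed comparative advantage of genes within cells
#'
#' RCA compares a cell's expression share of a gene with that gene's global
#' share of all expression: entry (c, g) is (x_cg / cell c total) divided by
#' (gene g total / grand total). RCA > 1 marks genes a cell expresses more
#' prominently than the "average" cell does. Zero entries have RCA 0, and the
#' expression-share-weighted mean of RCA within each cell is exactly 1.
#'
#' @param m Cells x genes matrix with positive grand total.
#' @return Base matrix of RCA values with the input dimnames and attribute
#'   `threshold` (the conventional advantage cutoff, 1).
#' @export
gene_rca <- function(m) {
  m <- as_expression_matrix(m)
  grand <- sum(m)
  if (grand <= 0) stop("zero grand total: RCA undefined", call. = FALSE)
  cell_tot <- row_sums(m)
  gene_tot <- col_sums(m)
  share_cell <- as.matrix(m) / ifelse(cell_tot > 0, cell_tot, 1)
  share_gene <- gene_tot / grand
  rca <- t(t(share_cell) / ifelse(share_gene > 0, share_gene, 1))
  rca[, gene_tot == 0] <- 0
  dimnames(rca) <- dimnames(m)
  attr(rca, "threshold") <- 1
  rca
}

#' Gene-gene proximity network
#'
#' The proximity of genes i and j is the smaller of the two conditional
#' probabilities that a cell holds a significant advantage (RCA at or above
#' `threshold`) in one gene given that it does in the other. Taking the
#' minimum keeps the measure symmetric and conservative: proximity never
#' exceeds either conditional. Genes with no advantaged cell anywhere have
#' undefined conditionals (0/0); they get proximity 0 to every gene
#' (including themselves) and are flagged, not dropped silently.
#'
#' @param rca RCA matrix from [gene_rca()], or a cells x genes expression
#'   matrix (RCA is computed first).
#' @param threshold Advantage cutoff; default 1.
#' @return An object of class `sctc_gene_space`: list with the symmetric
#'   `proximity` matrix (diagonal 1 for advantaged genes), logical
#'   `advantaged` flag per gene, `threshold`, and `mst_edges` (`NULL` until
#'   [max_spanning_tree()] is called).
#' @export
gene_proximity <- function(rca, threshold = 1) {
  if (!is.matrix(rca) || is.null(attr(rca, "threshold"))) rca <- gene_rca(rca)
  adv <- rca >= threshold                 # cells x genes advantage indicator
  n_adv <- colSums(adv)
  if (all(n_adv == 0)) stop("no gene reaches the RCA threshold anywhere", call. = FALSE)
  co <- crossprod(adv * 1)                # co-advantage counts
  # phi_ij = min(co/n_i, co/n_j) = co / pmax(n_i, n_j); guard 0/0 -> 0
  denom <- outer(n_adv, n_adv, pmax)
  phi <- ifelse(denom > 0, co / denom, 0)
  dimnames(phi) <- list(colnames(rca), colnames(rca))
  if (any(n_adv == 0)) {
    warning(sum(n_adv == 0), " gene(s) are never advantaged; proximity set to 0 and flagged",
            call. = FALSE)
  }
  structure(list(proximity = phi,
                 advantaged = stats::setNames(n_adv > 0, colnames(rca)),
                 threshold = threshold,
                 mst_edges = NULL),
            class = "sctc_gene_space")
}

# Kruskal with explicit deterministic tie-break: edges sorted by weight
# descending, then by (i, j) index ascending. Returns a maximum spanning
# forest (one tree per connected component of the positive-proximity graph).
kruskal_max_forest <- function(phi) {
  n <- nrow(phi)
  idx <- which(upper.tri(phi) & phi > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(tibble::tibble(gene_i = character(), gene_j = character(), weight = numeric()))
  }
  w <- phi[idx]
  ord <- order(-w, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  w <- w[ord]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- logical(length(w))
  for (e in seq_along(w)) {
    ri <- find(idx[e, 1])
    rj <- find(idx[e, 2])
    if (ri != rj) {
      parent[ri] <- rj
      keep[e] <- TRUE
    }
  }
  tibble::tibble(gene_i = rownames(phi)[idx[keep, 1]],
                 gene_j = rownames(phi)[idx[keep, 2]],
                 weight = w[keep])
}

#' Maximum spanning tree of the gene space
#'
#' Computes, for each connected component of the positive-proximity graph over
#' advantaged genes, the spanning tree maximizing total proximity (a maximum
#' spanning forest overall). Ties are broken deterministically by sorting
#' edges on (weight descending, gene index pair ascending) before the greedy
#' pass, so repeated runs give identical edge lists.
#'
#' @param space An `sctc_gene_space` object.
#' @return The same object with `mst_edges` populated: a tibble with columns
#'   `gene_i`, `gene_j`, `weight`.
#' @export
max_spanning_tree <- function(space) {
  stopifnot(inherits(space, "sctc_gene_space"))
  phi <- space$proximity
  phi_adv <- phi[space$advantaged, space$advantaged, drop = FALSE]
  space$mst_edges <- kruskal_max_forest(phi_adv)
  space
}

#' Gene degrees in the gene space
#'
#' Degree of each gene in the chosen graph: edge count in the
#' positive-proximity graph thresholded at `threshold` (default, edges with
#' proximity > 0), weighted degree (strength, the sum of proximities) in the
#' `"full"` graph, or edge count in the maximum spanning tree. The
#' thresholded graph is the default because tree degrees are nearly constant
#' and uninformative, while graph degree reflects how centrally a gene sits
#' among co-advantaged genes.
#'
#' @param space An `sctc_gene_space` object (with `mst_edges` populated if
#'   `graph = "mst"`).
#' @param graph `"threshold"`, `"full"` (weighted degree) or `"mst"`.
#' @param threshold Proximity cutoff for `graph = "threshold"`; default 0
#'   (any positive proximity is an edge).
#' @return Named numeric vector of degrees per gene (integer counts for
#'   `"threshold"` and `"mst"`).
#' @export
gene_degree <- function(space, graph = c("threshold", "full", "mst"), threshold = 0) {
  stopifnot(inherits(space, "sctc_gene_space"))
  graph <- match.arg(graph)
  genes <- rownames(space$proximity)
  if (graph == "threshold") {
    adj <- space$proximity > threshold
    diag(adj) <- FALSE
    deg <- as.numeric(rowSums(adj))
  } else if (graph == "full") {
    phi <- space$proximity
    diag(phi) <- 0
    deg <- rowSums(phi)
  } else {
    if (is.null(space$mst_edges)) stop("run max_spanning_tree() first", call. = FALSE)
    deg <- as.numeric(table(factor(c(space$mst_edges$gene_i, space$mst_edges$gene_j),
                                   levels = genes)))
  }
  stats::setNames(deg, genes)
}

#' Mean degree of the genes a cell expresses
#'
#' For each cell, the average gene-space degree over the genes with nonzero
#' expression in that cell. Cells whose complexity is high tend to express
#' genes sitting in the well-connected core of the gene space, so this
#' statistic tracks the complexity index more closely than raw diversity.
#'
#' @param m Cells x genes matrix (gene set must match the gene space).
#' @param space An `sctc_gene_space` object.
#' @inheritParams gene_degree
#' @return Named numeric vector per cell.
#' @export
mean_expressed_degree <- function(m, space, graph = c("threshold", "full", "mst"), threshold = 0) {
  m <- as_expression_matrix(m)
  stopifnot(inherits(space, "sctc_gene_space"))
  genes <- rownames(space$proximity)
  if (!identical(colnames(m), genes)) {
    if (!all(colnames(m) %in% genes)) stop("matrix genes not covered by the gene space", call. = FALSE)
  }
  deg <- gene_degree(space, graph = graph, threshold = threshold)[colnames(m)]
  expressed <- as.matrix(m > 0)
  n_expr <- rowSums(expressed)
  if (any(n_expr == 0)) stop("cell expressing no genes; run filter_empty() first", call. = FALSE)
  stats::setNames(as.numeric(expressed %*% deg) / n_expr, rownames(m))
}

#' @export
print.sctc_gene_space <- function(x, ...) {
  cat("<sctc_gene_space> ", nrow(x$proximity), " genes, ",
      sum(x$advantaged), " advantaged (RCA >= ", x$threshold, ")", sep = "")
  if (!is.null(x$mst_edges)) cat(", MST with ", nrow(x$mst_edges), " edges", sep = "")
  cat("\n")
  invisible(x)
}
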