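#' Spearman correlation between a score vector and stage labels
#'
#' Stages are coded 0..K-1 in the declared order (`stage_order`, or factor
#' levels / sorted unique labels when absent); the correlation uses average
#' ranks within exact ties, the standard Spearman treatment.
#'
#' @param scores Numeric vector, one score per cell (e.g. pseudotime).
#' @param stages Stage label per cell.
#' @param stage_order Optional character vector giving the temporal order of
#'   the labels. Label order is never inferred from label text.
#' @return Spearman correlation in \[-1, 1\].
#' @export
scc_vs_labels <- function(scores, stages, stage_order = NULL) {
  if (length(scores) != length(stages)) stop("`scores` and `stages` lengths differ", call. = FALSE)
  codes <- stage_codes(stages, stage_order)
  if (length(unique(codes)) < 2L) stop("fewer than 2 distinct stages: correlation undefined",
                                       call. = FALSE)
  spearman(scores, codes)
}

#' Diversity-based pseudotime baseline
#'
#' The transcriptional-diversity baseline: the number of expressed genes per
#' cell, min-max normalized. Its complement `1 - value` is the baseline
#' pseudotime under the assumption that diversity falls monotonically during
#' differentiation. This is a deliberately simple stand-in for
#' diversity-based potency scores; it is not a reimplementation of any
#' published tool.
#'
#' @param m Cells x genes matrix.
#' @param as_pseudotime Return `1 - normalized diversity` instead. Default
#'   `FALSE`.
#' @return Named numeric vector per cell in \[0, 1\].
#' @export
diversity_baseline <- function(m, as_pseudotime = FALSE) {
  m <- as_expression_matrix(m)
  d <- as.numeric(Matrix::rowSums(m > 0))
  v <- minmax(d, what = "expressed-gene count")
  if (as_pseudotime) v <- 1 - v
  stats::setNames(v, rownames(m))
}

# per-cell mean gene complexity: average of a gene-complexity column over the
# genes each cell expresses
mean_gene_complexity <- function(m, gene_col) {
  expressed <- as.matrix(m > 0)
  as.numeric(expressed %*% gene_col) / rowSums(expressed)
}

#' Silhouette of stage separation across complexity orders
#'
#' For each requested odd order N, the per-cell feature is the mean gene
#' complexity (average of the order-N gene column over the genes the cell
#' expresses); order 0 denotes the diversity feature (expressed-gene count).
#' The silhouette coefficient of the stage partition is computed on each
#' one-dimensional feature; stages with a single cell are excluded with a
#' warning. Silhouette is invariant under affine transforms of the feature
#' and under relabeling, so normalization and the temporal direction of the
#' labels do not affect it.
#'
#' @param refl An `sctc_reflections` object with the needed gene orders.
#' @param m The matrix the reflections were computed from.
#' @param stages Stage label per cell.
#' @param orders Integer orders to evaluate; default `c(0, seq(1, min(n_max, 11), 2))`.
#' @return A tibble with columns `order` and `silhouette`.
#' @export
silhouette_over_orders <- function(refl, m, stages, orders = NULL) {
  stopifnot(inherits(refl, "sctc_reflections"))
  m <- as_expression_matrix(m, require_nonempty_margins = TRUE)
  if (length(stages) != nrow(m)) stop("`stages` must have one label per cell", call. = FALSE)
  if (is.null(orders)) orders <- c(0L, seq(1L, min(refl$n_max, 11L), by = 2L))
  if (any(orders > refl$n_max)) stop("requested order exceeds the computed n_max", call. = FALSE)
  f <- factor(stages)
  small <- names(table(f))[table(f) < 2L]
  if (length(small)) {
    warning("excluding single-cell stage(s): ", paste(small, collapse = ", "), call. = FALSE)
    keep <- !(f %in% small)
    m <- m[keep, , drop = FALSE]
    f <- droplevels(f[keep])
  }
  cl <- as.integer(f)
  sil <- vapply(orders, function(N) {
    feat <- if (N == 0L) {
      as.numeric(Matrix::rowSums(m > 0))
    } else {
      mean_gene_complexity(m, refl$gene_raw[, N + 1L])
    }
    mean(cluster::silhouette(cl, stats::dist(matrix(feat, ncol = 1)))[, 3])
  }, numeric(1))
  tibble::tibble(order = as.integer(orders), silhouette = sil)
}

#' Rank genes by a complexity metric
#'
#' Genes sorted in descending order of the chosen metric (an order-N gene
#' column of a reflections table, or GCI from an index object); ties keep
#' input order (stable sort). Rank 1 is the most complex gene.
#'
#' @param x An `sctc_reflections` or `sctc_complexity` object.
#' @param metric For reflections: integer order N. For indices: `"gci"`
#'   (default).
#' @return A tibble with columns `gene`, `value`, `rank`.
#' @export
rank_genes_by_metric <- function(x, metric = "gci") {
  if (inherits(x, "sctc_reflections")) {
    if (!is.numeric(metric)) stop("for reflections, `metric` is an integer order N", call. = FALSE)
    v <- x$gene_raw[, metric + 1L]
    genes <- rownames(x$gene_raw)
  } else if (inherits(x, "sctc_complexity")) {
    if (!identical(metric, "gci")) stop("for indices, `metric` must be \"gci\"", call. = FALSE)
    v <- x$genes$gci
    genes <- x$genes$gene
    if (all(is.na(v))) stop("GCI not populated; run gci_from_cci()", call. = FALSE)
  } else {
    stop("`x` must be sctc_reflections or sctc_complexity", call. = FALSE)
  }
  ord <- order(-v)  # stable: ties keep input order
  tibble::tibble(gene = genes[ord], value = unname(v[ord]), rank = seq_along(ord))
}

#' Stage markers by rank-sum differential expression
#'
#' Convenience marker detection: for each stage, genes are scored by a
#' Wilcoxon rank-sum test of that stage's cells against all other cells
#' (one-sided, greater), and the `n_top` most significant genes are reported.
#' This is an approximate, self-contained marker caller intended for the
#' concordance protocol, not a substitute for a dedicated DE framework.
#'
#' @param m Cells x genes matrix.
#' @param stages Stage label per cell.
#' @param n_top Markers per stage. Default 10.
#' @return A tibble with columns `stage`, `gene`, `p_value`.
#' @export
find_stage_markers <- function(m, stages, n_top = 10) {
  m <- as_expression_matrix(m)
  if (length(stages) != nrow(m)) stop("`stages` must have one label per cell", call. = FALSE)
  f <- factor(stages)
  mm <- as.matrix(m)
  res <- lapply(levels(f), function(s) {
    in_s <- f == s
    p <- apply(mm, 2L, function(x) {
      stats::wilcox.test(x[in_s], x[!in_s], alternative = "greater", exact = FALSE)$p.value
    })
    ord <- order(p)[seq_len(min(n_top, length(p)))]
    tibble::tibble(stage = s, gene = colnames(mm)[ord], p_value = unname(p[ord]))
  })
  dplyr::bind_rows(res)
}

#' Concordance of marker-gene rankings with stage order
#'
#' For each provided gene ranking, computes the Spearman correlation between
#' the marker genes' rank positions and their stages' temporal codes. Early
#' stages are expected at the top of a complexity ranking (small rank), so a
#' correct ranking yields a strongly positive correlation. Markers missing
#' from a ranking are excluded with a warning.
#'
#' @param markers Tibble with columns `stage` and `gene` (e.g. from
#'   [find_stage_markers()]).
#' @param rankings A single ranking tibble from [rank_genes_by_metric()], or
#'   a named list of them.
#' @param stage_order Optional temporal order of stage labels.
#' @return A tibble with columns `metric` and `scc`.
#' @export
marker_stage_concordance <- function(markers, rankings, stage_order = NULL) {
  if (!is.data.frame(markers) || !all(c("stage", "gene") %in% names(markers))) {
    stop("`markers` needs columns stage, gene", call. = FALSE)
  }
  if (is.data.frame(rankings)) rankings <- list(ranking = rankings)
  codes <- stage_codes(markers$stage, stage_order)
  out <- lapply(names(rankings), function(nm) {
    rk <- rankings[[nm]]
    pos <- rk$rank[match(markers$gene, rk$gene)]
    miss <- is.na(pos)
    if (any(miss)) warning(sum(miss), " marker(s) absent from ranking '", nm, "'; excluded",
                           call. = FALSE)
    tibble::tibble(metric = nm, scc = spearman(pos[!miss], codes[!miss]))
  })
  dplyr::bind_rows(out)
}

#' Simulate dropout
#'
#' Each nonzero entry is independently set to zero with probability `rate`;
#' all-zero cells and genes created by the zeroing are then removed (set
#' `filter = FALSE` to keep them). The seed fully determines the output.
#'
#' @param m Cells x genes matrix.
#' @param rate Dropout probability in \[0, 1\].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param filter Apply [filter_empty()] afterwards. Default `TRUE`.
#' @return Matrix after dropout (and filtering).
#' @export
dropout_simulate <- function(m, rate, seed = NULL, filter = TRUE) {
  m <- as_expression_matrix(m)
  if (!is.numeric(rate) || rate < 0 || rate > 1) stop("`rate` must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- as.matrix(m)
  nz <- which(out != 0)
  drop <- nz[stats::runif(length(nz)) < rate]
  out[drop] <- 0
  if (filter) out <- filter_empty(out)
  out
}

#' Pseudotime accuracy under increasing dropout
#'
#' For each dropout rate and repeat, simulates dropout, recomputes the
#' complexity (CCI) pseudotime and the diversity-baseline pseudotime on the
#' surviving cells, and scores each against the stage labels with Spearman
#' correlation. Returns per-rate mean and standard deviation per method.
#'
#' @param m Cells x genes matrix.
#' @param stages Stage label per cell (aligned with rows of `m`).
#' @param rates Numeric vector of dropout rates.
#' @param repeats Simulations per rate. Default 10.
#' @param seed Base seed; repeat r at rate index i uses
#'   `seed + 1000 * i + r`.
#' @param stage_order Optional temporal order of stage labels.
#' @return An object of class `sctc_robustness`: a tibble with columns
#'   `rate`, `method`, `mean_scc`, `sd_scc`, and the per-repeat detail in
#'   attribute `detail`.
#' @export
robustness_curve <- function(m, stages, rates, repeats = 10, seed = 1,
                             stage_order = NULL) {
  m <- as_expression_matrix(m)
  if (length(stages) != nrow(m)) stop("`stages` must have one label per cell", call. = FALSE)
  if (repeats < 1) stop("`repeats` must be >= 1", call. = FALSE)
  stages <- as.character(stages)
  names(stages) <- rownames(m)
  detail <- list()
  for (i in seq_along(rates)) {
    for (r in seq_len(repeats)) {
      md <- dropout_simulate(m, rates[i], seed = seed + 1000L * i + r)
      st <- stages[rownames(md)]
      scc_sctc <- scc_vs_labels(pseudotime(sctc_cci(md, compute_gci = FALSE)), st, stage_order)
      scc_div <- scc_vs_labels(diversity_baseline(md, as_pseudotime = TRUE), st, stage_order)
      detail[[length(detail) + 1L]] <- tibble::tibble(
        rate = rates[i], repeat_id = r,
        method = c("sctc", "diversity"), scc = c(scc_sctc, scc_div))
    }
  }
  detail <- dplyr::bind_rows(detail)
  out <- detail |>
    dplyr::group_by(.data$rate, .data$method) |>
    dplyr::summarise(mean_scc = mean(.data$scc),
                     sd_scc = stats::sd(.data$scc), .groups = "drop")
  attr(out, "detail") <- detail
  class(out) <- c("sctc_robustness", class(out))
  out
}
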