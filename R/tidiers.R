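#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reflections table
#'
#' Long tibble with one row per node and order: columns `id`, `kind`
#' (`"cell"`/`"gene"`), `order`, `complexity` (normalized if the table was
#' computed with `normalize = TRUE`) and `complexity_raw`.
#'
#' @param x An `sctc_reflections` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sctc_reflections
#' @export
tidy.sctc_reflections <- function(x, ...) {
  long <- function(mat, raw, kind) {
    tibble::tibble(
      id = rep(rownames(mat), times = ncol(mat)),
      kind = kind,
      order = rep(0:(ncol(mat) - 1L), each = nrow(mat)),
      complexity = as.numeric(mat),
      complexity_raw = as.numeric(raw)
    )
  }
  dplyr::bind_rows(long(x$cell, x$cell_raw, "cell"),
                   long(x$gene, x$gene_raw, "gene"))
}

#' @rdname tidy.sctc_reflections
#' @method glance sctc_reflections
#' @export
glance.sctc_reflections <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$cell), n_genes = nrow(x$gene),
                 n_max = x$n_max, normalized = x$normalized)
}

#' Tidy complexity indices
#'
#' @param x An `sctc_complexity` object.
#' @param what `"cells"` (cell, diversity, cci, pseudotime) or `"genes"`
#'   (gene, ubiquity, gci).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sctc_complexity
#' @export
tidy.sctc_complexity <- function(x, what = c("cells", "genes"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' @rdname tidy.sctc_complexity
#' @method glance sctc_complexity
#' @export
glance.sctc_complexity <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$cells), n_genes = nrow(x$genes),
                 second_eigenvalue = x$second_eigenvalue,
                 eigen_gap = x$eigen_gap,
                 sign_scc = x$sign_scc,
                 transferred = isTRUE(x$transferred))
}

#' Tidy a gene space
#'
#' `what = "edges"` returns the maximum-spanning-tree edge list (requires
#' [max_spanning_tree()]); `what = "proximity"` the long upper-triangle of
#' the proximity matrix; `what = "genes"` per-gene degree and advantage flag.
#'
#' @param x An `sctc_gene_space` object.
#' @param what `"edges"`, `"proximity"` or `"genes"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sctc_gene_space
#' @export
tidy.sctc_gene_space <- function(x, what = c("edges", "proximity", "genes"), ...) {
  what <- match.arg(what)
  if (what == "edges") {
    if (is.null(x$mst_edges)) stop("run max_spanning_tree() first", call. = FALSE)
    return(x$mst_edges)
  }
  if (what == "proximity") {
    ut <- which(upper.tri(x$proximity), arr.ind = TRUE)
    return(tibble::tibble(gene_i = rownames(x$proximity)[ut[, 1]],
                          gene_j = colnames(x$proximity)[ut[, 2]],
                          proximity = x$proximity[ut]))
  }
  tibble::tibble(gene = rownames(x$proximity),
                 advantaged = unname(x$advantaged),
                 degree = unname(gene_degree(x)))
}
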