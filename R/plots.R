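#' Pseudotime distribution by developmental stage
#'
#' Boxplots of a pseudotime vector split by stage, the standard visual check
#' that the inferred ordering follows the annotated time course.
#'
#' @param scores Named numeric pseudotime per cell, or an `sctc_complexity`
#'   object.
#' @param stages Stage label per cell (aligned with `scores`).
#' @param stage_order Optional temporal order of the labels.
#' @return A ggplot object.
#' @export
plot_pseudotime <- function(scores, stages, stage_order = NULL) {
  if (inherits(scores, "sctc_complexity")) scores <- pseudotime(scores)
  if (is.null(stage_order)) stage_order <- sort(unique(as.character(stages)))
  df <- tibble::tibble(stage = factor(as.character(stages), levels = stage_order),
                       pseudotime = as.numeric(scores))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$pseudotime)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::labs(x = "stage", y = "pseudotime (1 - CCI)") +
    ggplot2::theme_minimal()
}

#' Diversity-complexity diagram
#'
#' Scatter of per-cell diversity (expressed-gene count) against mean gene
#' complexity (average GCI over expressed genes), coloured by stage, with
#' dashed lines at the grand means. Early cells typically sit in the
#' low-diversity / high-complexity quadrant in the hard regime.
#'
#' @param m Cells x genes matrix.
#' @param indices `sctc_complexity` object with GCI populated.
#' @param stages Stage label per cell.
#' @return A ggplot object.
#' @export
plot_diversity_complexity <- function(m, indices, stages) {
  m <- as_expression_matrix(m)
  stopifnot(inherits(indices, "sctc_complexity"))
  gci <- stats::setNames(indices$genes$gci, indices$genes$gene)[colnames(m)]
  df <- tibble::tibble(
    diversity = as.numeric(Matrix::rowSums(m > 0)),
    complexity = mean_gene_complexity(m, gci),
    stage = factor(stages)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diversity, y = .data$complexity,
                                   colour = .data$stage)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_vline(xintercept = mean(df$diversity), linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = mean(df$complexity), linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "gene diversity (expressed genes)", y = "mean gene complexity (GCI)") +
    ggplot2::theme_minimal()
}

#' Silhouette coefficient across complexity orders
#'
#' @param sil Tibble from [silhouette_over_orders()].
#' @return A ggplot object.
#' @export
plot_silhouette_orders <- function(sil) {
  ggplot2::ggplot(sil, ggplot2::aes(x = .data$order, y = .data$silhouette)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "complexity order N (0 = diversity)", y = "mean silhouette") +
    ggplot2::theme_minimal()
}

#' Dropout robustness curves
#'
#' Mean Spearman accuracy against stage labels per dropout rate, with a
#' ribbon of one standard deviation across repeats, for the complexity
#' method and the diversity baseline.
#'
#' @param object An `sctc_robustness` tibble from [robustness_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sctc_robustness
#' @export
autoplot.sctc_robustness <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rate, y = .data$mean_scc,
                                       colour = .data$method, fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_scc - .data$sd_scc,
                                      ymax = .data$mean_scc + .data$sd_scc),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "dropout rate", y = "SCC vs stage labels") +
    ggplot2::theme_minimal()
}

#' @rdname plot_pseudotime
#' @param object An `sctc_complexity` object.
#' @param ... Passed on; supply `stages` to stratify.
#' @method autoplot sctc_complexity
#' @export
autoplot.sctc_complexity <- function(object, stages = NULL, ...) {
  if (!is.null(stages)) return(plot_pseudotime(object, stages, ...))
  df <- object$cells
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diversity, y = .data$cci)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "diversity (k0)", y = "CCI") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
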