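#' Heatmap of a fitted bicluster
#'
#' Shows the selected genes across all cells, with the in-cluster cells
#' first, so that marker specificity (high expression inside, little
#' outside) is visible at a glance.
#'
#' @param object A `rarebic_bicluster` with `found = TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rarebic_bicluster
#' @export
autoplot.rarebic_bicluster <- function(object, ...) {
  if (!object$found) {
    abort("Nothing to plot: no feasible bicluster was found.",
          class = "rarebic_error_param")
  }
  m <- object$expression
  cell_order <- c(object$cells, setdiff(colnames(m), object$cells))
  df <- tibble(
    gene = rep(rownames(m), times = ncol(m)),
    cell = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
  df$cell <- factor(df$cell, levels = cell_order)
  df$gene <- factor(df$gene, levels = rev(rownames(m)))
  df$in_cluster <- df$cell %in% object$cells
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$gene,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_vline(xintercept = length(object$cells) + 0.5,
                        linewidth = 0.8) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = "log-expr") +
    ggplot2::labs(x = "cells (selected first)", y = "selected genes",
                  title = sprintf("Bicluster: %d cells x %d genes, objective %.4g",
                                  length(object$cells), length(object$genes),
                                  object$objective)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Per-run metrics of a controlled experiment
#'
#' @param object A `rarebic_eval`.
#' @param ... Unused.
#' @return A ggplot object showing precision, recall and F1 per run.
#' @method autoplot rarebic_eval
#' @export
autoplot.rarebic_eval <- function(object, ...) {
  df <- tidyr_longer(object$per_run)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$run, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "run", y = NULL,
                  title = sprintf("Planted-subpopulation recovery (top-%d, %d runs)",
                                  object$k, object$n_runs)) +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (precision/recall/f1 columns)
tidyr_longer <- function(per_run) {
  dplyr::bind_rows(
    tibble(run = per_run$run, metric = "precision", value = per_run$precision),
    tibble(run = per_run$run, metric = "recall", value = per_run$recall),
    tibble(run = per_run$run, metric = "f1", value = per_run$f1)
  )
}
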