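#' Search parameters for the constrained bicluster optimization
#'
#' Bundles the tuning parameters of the objective and of the breadth-first
#' beam search.
#'
#' @param kappa Non-negative weight of the out-of-cluster penalty: the
#'   objective of a bicluster (I, J) is
#'   `sum_{i in I} ( sum_{j in J} m_ij - kappa * sum_{k not in J} max(0, m_ik) )`.
#'   The higher `kappa`, the fewer genes are selected. `NULL` (default)
#'   resolves to `100 / n_cells` when a matrix is supplied.
#' @param mu Maximum allowed fraction of negative entries inside the
#'   bicluster, in `[0, 1]`; default 0.10. This tolerance is what lets a
#'   solution absorb dropout zeros.
#' @param max_prevalence Gene prevalence filter threshold used by [top_k()]
#'   when re-filtering between rounds; default 0.25.
#' @param min_cells Minimum number of cells in a returned bicluster
#'   (at least 2; the search starts from cell pairs).
#' @param max_cells Maximum number of cells to consider (`Inf` = all).
#' @param beam_width Number of cell subsets retained per level of the
#'   breadth-first search; default 100.
#' @param patience Number of consecutive levels without improvement of the
#'   best feasible objective before the search stops (counted only once a
#'   feasible bicluster exists); default 2.
#' @param top_k Default number of rounds for [top_k()]; default 1.
#'
#' @return A list of class `rarebic_params`.
#' @export
bicluster_params <- function(kappa = NULL, mu = 0.1, max_prevalence = 0.25,
                             min_cells = 2L, max_cells = Inf,
                             beam_width = 100L, patience = 2L, top_k = 1L) {
  if (!is.null(kappa) && (!is.numeric(kappa) || length(kappa) != 1L || kappa < 0)) {
    abort("`kappa` must be a single non-negative number (or NULL for 100/n_cells).",
          class = "rarebic_error_param")
  }
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0 || mu > 1) {
    abort("`mu` must be a single fraction in [0, 1].", class = "rarebic_error_param")
  }
  min_cells <- as.integer(min_cells)
  if (min_cells < 2L) {
    abort("`min_cells` must be at least 2.", class = "rarebic_error_param")
  }
  if (max_cells < min_cells) {
    abort("`max_cells` must be >= `min_cells`.", class = "rarebic_error_param")
  }
  beam_width <- max(1, beam_width)
  if (top_k < 1L) abort("`top_k` must be >= 1.", class = "rarebic_error_param")
  structure(
    list(kappa = kappa, mu = mu, max_prevalence = max_prevalence,
         min_cells = min_cells, max_cells = max_cells,
         beam_width = beam_width, patience = patience,
         top_k = as.integer(top_k)),
    class = "rarebic_params"
  )
}

resolve_kappa <- function(params, n_cells) {
  params$kappa %||% (100 / n_cells)
}

#' @export
print.rarebic_params <- function(x, ...) {
  cat("<rarebic_params>\n")
  cat(sprintf("  kappa: %s   mu: %g   max_prevalence: %g\n",
              if (is.null(x$kappa)) "100/n_cells" else format(x$kappa),
              x$mu, x$max_prevalence))
  cat(sprintf("  cells: [%d, %s]   beam_width: %d   patience: %d   top_k: %d\n",
              x$min_cells, format(x$max_cells), as.integer(x$beam_width),
              as.integer(x$patience), x$top_k))
  invisible(x)
}
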