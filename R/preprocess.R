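#' Log-normalize raw counts
#'
#' Replaces every raw count `x` by `log10(x + pseudo)`. With the default
#' pseudo-count of 0.1, a raw value of 0.9 maps exactly to 0, so that
#' "expressed" (normalized value > 0) corresponds to a raw count above 0.9.
#' Zeros map to `log10(pseudo)` (-1 by default), making non-expression
#' negative, which is what the downstream bicluster objective and the
#' negative-entry constraint assume.
#'
#' @param raw Raw count matrix (non-negative), as accepted by
#'   [expression_matrix()].
#' @param pseudo Positive pseudo-count added before taking `log10`. The raw
#'   expression threshold is `1 - pseudo` on the count scale when the cutoff
#'   "normalized value > 0" is used.
#' @param threshold Optional explicit raw expression threshold `t`: when
#'   given, `log10(t + pseudo)` is subtracted so that "expressed" means
#'   raw value > `t` instead. Off by default.
#' @param force Set `TRUE` to normalize a matrix that already contains
#'   negative values (normally refused, since a second log-transform silently
#'   corrupts the data).
#'
#' @return A normalized [expression_matrix()].
#' @examples
#' m <- expression_matrix(matrix(c(0, 0.9, 99.9, 9.9), 2, 2))
#' log_normalize(m)
#' @export
log_normalize <- function(raw, pseudo = 0.1, threshold = NULL, force = FALSE) {
  if (!is.numeric(pseudo) || length(pseudo) != 1L || !is.finite(pseudo) || pseudo <= 0) {
    abort("`pseudo` must be a single positive number.", class = "rarebic_error_param")
  }
  m <- as_expr_matrix(raw)
  if (is_normalized(m) && !force) {
    abort(paste0("Matrix already contains negative values and looks normalized; ",
                 "refusing to log-transform again (use `force = TRUE` to override)."),
          class = "rarebic_error_input")
  }
  v <- unclass_expr(m)
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1L, ]
    abort(sprintf("Negative raw entry for gene '%s' in cell '%s'.",
                  rownames(v)[bad[[1L]]], colnames(v)[bad[[2L]]]),
          class = "rarebic_error_input")
  }
  out <- log10(v + pseudo)
  if (!is.null(threshold)) {
    if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
      abort("`threshold` must be a single non-negative number.",
            class = "rarebic_error_param")
    }
    out <- out - log10(threshold + pseudo)
  }
  expression_matrix(out, normalized = TRUE)
}

#' Filter out broadly expressed genes
#'
#' Removes genes expressed (normalized value strictly > 0) in more than
#' `max_prevalence` of the cells. Solutions of the bicluster search are meant
#' to be specific to a small subpopulation; genes expressed across a large
#' share of all cells cannot be specific markers and would otherwise dominate
#' the max-sum objective. The boundary is inclusive: a gene expressed in
#' exactly `max_prevalence` of the cells is kept.
#'
#' @param M Normalized expression matrix.
#' @param max_prevalence Fraction in (0, 1]; default 0.25. `1` removes
#'   nothing.
#'
#' @return The filtered matrix, with the removed gene names available via
#'   [removed_genes()].
#' @seealso [removed_genes()]
#' @export
filter_genes <- function(M, max_prevalence = 0.25) {
  if (!is.numeric(max_prevalence) || length(max_prevalence) != 1L ||
      max_prevalence <= 0 || max_prevalence > 1) {
    abort("`max_prevalence` must be a single fraction in (0, 1].",
          class = "rarebic_error_param")
  }
  m <- as_expr_matrix(M)
  if (!is_normalized(m)) {
    abort("`filter_genes()` expects a normalized matrix; run `log_normalize()` first.",
          class = "rarebic_error_input")
  }
  v <- unclass_expr(m)
  prevalence <- rowMeans(v > 0)
  drop <- prevalence > max_prevalence
  if (all(drop)) {
    abort(paste0("All genes are expressed in more than ",
                 format(100 * max_prevalence), "% of the cells; ",
                 "raise `max_prevalence` to keep at least one gene."),
          class = "rarebic_error_empty")
  }
  out <- expression_matrix(v[!drop, , drop = FALSE], normalized = TRUE)
  attr(out, "removed_genes") <- rownames(v)[drop]
  out
}

#' Genes removed by the prevalence filter
#'
#' @param M A matrix returned by [filter_genes()].
#' @return Character vector of removed gene names (empty if none recorded).
#' @export
removed_genes <- function(M) {
  attr(M, "removed_genes") %||% character(0)
}
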