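#' Construct an expression matrix
#'
#' The canonical in-memory container of the package: a numeric matrix with
#' genes as rows and cells as columns. The matrix is either *raw* (non-negative
#' counts, `normalized = FALSE`) or *normalized* (signed log-expression,
#' `normalized = TRUE`). On a normalized matrix a strictly positive entry means
#' the gene is expressed in that cell; a non-positive entry means it is
#' negligibly expressed or not at all.
#'
#' @param values Numeric matrix (genes x cells). A data frame of numeric
#'   columns is accepted and converted.
#' @param gene_names,cell_names Unique row/column identifiers. Default to the
#'   dimnames of `values`; generated (`g1..`, `c1..`) when absent.
#' @param normalized Logical. `NULL` (default) infers the state: a matrix
#'   containing negative entries is treated as already normalized, an
#'   all-non-negative matrix as raw counts.
#'
#' @return A numeric matrix of class `expr_mat` with a `normalized` attribute.
#' @examples
#' m <- expression_matrix(matrix(rpois(12, 4), 3, 4))
#' is_normalized(m)
#' @export
expression_matrix <- function(values, gene_names = NULL, cell_names = NULL,
                              normalized = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x cells).",
          class = "rarebic_error_input")
  }
  gene_names <- gene_names %||% rownames(values) %||% paste0("g", seq_len(nrow(values)))
  cell_names <- cell_names %||% colnames(values) %||% paste0("c", seq_len(ncol(values)))
  if (length(gene_names) != nrow(values) || length(cell_names) != ncol(values)) {
    abort("Row/column name lengths do not match the matrix dimensions.",
          class = "rarebic_error_input")
  }
  if (anyDuplicated(gene_names)) {
    abort(paste0("Duplicate gene names: ",
                 paste(unique(gene_names[duplicated(gene_names)]), collapse = ", ")),
          class = "rarebic_error_input")
  }
  if (anyDuplicated(cell_names)) {
    abort(paste0("Duplicate cell names: ",
                 paste(unique(cell_names[duplicated(cell_names)]), collapse = ", ")),
          class = "rarebic_error_input")
  }
  if (any(!is.finite(values))) {
    abort("Expression values must be finite (no NA/NaN/Inf).",
          class = "rarebic_error_input")
  }
  normalized <- normalized %||% any(values < 0)
  if (!normalized && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    abort(sprintf("Raw counts must be non-negative; negative value for gene '%s' in cell '%s'.",
                  gene_names[bad[[1L]]], cell_names[bad[[2L]]]),
          class = "rarebic_error_input")
  }
  dimnames(values) <- list(gene_names, cell_names)
  structure(values, normalized = isTRUE(normalized),
            class = c("expr_mat", class(matrix())))
}

#' @rdname expression_matrix
#' @param x An object to test or coerce.
#' @export
is_normalized <- function(x) {
  isTRUE(attr(x, "normalized") %||% any(x < 0))
}

#' Coerce to an expression matrix, validating as needed
#' @noRd
as_expr_matrix <- function(x, normalized = NULL) {
  if (inherits(x, "expr_mat") && is.null(normalized)) return(x)
  expression_matrix(unclass_expr(x), normalized = normalized %||% attr(x, "normalized"))
}

#' Strip the expr_mat class (plain matrix for fast internal arithmetic)
#' @noRd
unclass_expr <- function(x) {
  attr(x, "normalized") <- NULL
  attr(x, "removed_genes") <- NULL
  class(x) <- "matrix"
  x
}

#' @export
print.expr_mat <- function(x, ...) {
  state <- if (is_normalized(x)) "normalized (signed log-expression)" else "raw counts"
  cat(sprintf("<expr_mat> %d genes x %d cells, %s\n", nrow(x), ncol(x), state))
  rem <- attr(x, "removed_genes")
  if (!is.null(rem)) {
    cat(sprintf("  prevalence filter removed %d gene(s)\n", length(rem)))
  }
  pv <- x[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE]
  print(unclass_expr(pv))
  invisible(x)
}

# resolve gene/cell identifiers (names or integer indices) to integer indices
resolve_idx <- function(ids, pool, what) {
  if (is.numeric(ids)) {
    idx <- as.integer(ids)
    if (any(idx < 1L | idx > length(pool))) {
      abort(sprintf("%s index out of range.", what), class = "rarebic_error_lookup")
    }
    return(idx)
  }
  idx <- match(ids, pool)
  if (anyNA(idx)) {
    abort(sprintf("Unknown %s: %s", what,
                  paste(ids[is.na(idx)], collapse = ", ")),
          class = "rarebic_error_lookup")
  }
  idx
}
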