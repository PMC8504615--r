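#' Read an expression matrix from disk
#'
#' Dense TSV/CSV (first column = gene names, header = cell names) or a
#' MatrixMarket coordinate file with companion gene and barcode name files
#' (10x-style triplet). Whatever the on-disk orientation, the returned
#' matrix has genes as rows.
#'
#' @param path File path. For `mtx`, the sparse matrix file.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"mtx"`.
#' @param genes_as_rows Set `FALSE` when the on-disk table stores cells as
#'   rows; the matrix is transposed on read.
#' @param genes_file,cells_file Companion name files for `mtx` input.
#'   Default: `genes.tsv`/`features.tsv` and `barcodes.tsv` next to `path`.
#' @param normalized Passed to [expression_matrix()]; `NULL` infers from the
#'   sign of the values.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        genes_as_rows = TRUE,
                        genes_file = NULL, cells_file = NULL,
                        normalized = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "rarebic_error_io")
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     abort(sprintf("Cannot infer format from '%s'; pass `format=`.", path),
                           class = "rarebic_error_io"))
  }
  if (format == "mtx") {
    dir <- dirname(path)
    genes_file <- genes_file %||%
      Filter(file.exists, file.path(dir, c("genes.tsv", "features.tsv")))[1L]
    cells_file <- cells_file %||% file.path(dir, "barcodes.tsv")
    if (is.na(genes_file) || is.null(genes_file) || !file.exists(genes_file)) {
      abort("No gene name file found next to the .mtx (genes.tsv/features.tsv); pass `genes_file=`.",
            class = "rarebic_error_io")
    }
    if (!file.exists(cells_file)) {
      abort("No barcode file found next to the .mtx; pass `cells_file=`.",
            class = "rarebic_error_io")
    }
    sp <- Matrix::readMM(path)
    genes <- readr::read_tsv(genes_file, col_names = FALSE,
                             show_col_types = FALSE)[[1L]]
    cells <- readr::read_tsv(cells_file, col_names = FALSE,
                             show_col_types = FALSE)[[1L]]
    if (length(genes) != nrow(sp) || length(cells) != ncol(sp)) {
      abort(sprintf("Dimension mismatch: matrix is %d x %d but %d gene and %d cell names were read.",
                    nrow(sp), ncol(sp), length(genes), length(cells)),
            class = "rarebic_error_io")
    }
    dense <- as.matrix(sp)
    dimnames(dense) <- list(genes, cells)
    if (!genes_as_rows) dense <- t(dense)
    return(expression_matrix(dense, normalized = normalized))
  }
  delim <- if (format == "tsv") "\t" else ","
  tab <- readr::read_delim(path, delim = delim, col_names = TRUE,
                           show_col_types = FALSE, progress = FALSE)
  if (nrow(readr::problems(tab)) > 0) {
    abort(sprintf("Malformed table in %s (ragged rows or bad fields).", path),
          class = "rarebic_error_io")
  }
  if (ncol(tab) < 2L) {
    abort("Expected a name column plus at least one value column.",
          class = "rarebic_error_io")
  }
  row_names <- as.character(tab[[1L]])
  vals <- tab[, -1L, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
    abort(sprintf("Non-numeric entries in column(s): %s", paste(bad, collapse = ", ")),
          class = "rarebic_error_io")
  }
  mat <- as.matrix(vals)
  rownames(mat) <- row_names
  if (!genes_as_rows) mat <- t(mat)
  expression_matrix(mat, normalized = normalized)
}

#' Write an expression matrix as dense TSV/CSV
#'
#' @param M Matrix to write (genes as rows).
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @export
write_matrix <- function(M, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  m <- as_expr_matrix(M)
  df <- data.frame(gene = rownames(m), unclass_expr(m), check.names = FALSE)
  if (format == "tsv") {
    readr::write_tsv(df, path)
  } else {
    readr::write_csv(df, path)
  }
  invisible(path)
}

# assemble serializable records from solver output
result_records <- function(fit, params = NULL, input = NULL, seed = NULL) {
  fits <- if (inherits(fit, "rarebic_topk")) fit$results
          else if (inherits(fit, "rarebic_bicluster")) list(fit)
          else abort("`fit` must be a bicluster or top-k result.",
                     class = "rarebic_error_param")
  params <- params %||% (if (inherits(fit, "rarebic_topk")) fit$params else bicluster_params())
  prov <- list(
    input = input %||% NA_character_,
    input_md5 = if (!is.null(input) && file.exists(input))
      unname(tools::md5sum(input)) else NA_character_,
    tool = "rarebic",
    version = as.character(packageVersion("rarebic")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    list(rank = f$rank %||% i,
         cells = as.list(f$cells),
         genes = as.list(f$genes),
         objective = f$objective,
         negative_fraction = f$negative_fraction,
         params_echo = list(kappa = f$kappa, mu = f$mu,
                            max_prevalence = params$max_prevalence,
                            min_cells = params$min_cells,
                            max_cells = params$max_cells,
                            beam_width = params$beam_width,
                            patience = params$patience,
                            top_k = params$top_k,
                            seed = seed %||% NA_integer_),
         provenance = prov)
  })
}

#' Write solver results to JSON or TSV
#'
#' JSON is lossless (objectives carry full double precision) and can be read
#' back with [read_results()]; TSV flattens one bicluster per row with
#' comma-separated cell and gene lists.
#'
#' @param fit A `rarebic_bicluster` or `rarebic_topk` object — or a list of
#'   records from `result_records()`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @param input,seed Optional provenance (input file path, RNG seed) echoed
#'   into each record.
#' @export
write_results <- function(fit, path, format = c("json", "tsv"),
                          input = NULL, seed = NULL) {
  format <- match.arg(format)
  records <- if (is.list(fit) && !inherits(fit, c("rarebic_bicluster", "rarebic_topk")))
    fit else result_records(fit, input = input, seed = seed)
  if (format == "json") {
    jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
    # ensure trailing newline
    con <- file(path, open = "ab")
    on.exit(close(con))
    writeBin(charToRaw("\n"), con)
    return(invisible(path))
  }
  rows <- purrr::map_dfr(records, function(r) {
    tibble(rank = r$rank,
           n_cells = length(r$cells),
           n_genes = length(r$genes),
           objective = sprintf("%.12g", r$objective),
           negative_fraction = sprintf("%.12g", r$negative_fraction),
           cells = paste(unlist(r$cells), collapse = ","),
           genes = paste(unlist(r$genes), collapse = ","))
  })
  readr::write_tsv(rows, path)
  invisible(path)
}

#' Read back results written by [write_results()] (JSON only)
#'
#' @param path JSON results file.
#' @return A list of result records.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "rarebic_error_io")
  }
  jsonlite::read_json(path, simplifyVector = FALSE)
}
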