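#' Tidy a fitted bicluster
#'
#' One row per selected gene, with the gene's contribution statistics over
#' the selected cells (see [gene_stats()]).
#'
#' @param x A `rarebic_bicluster`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `in_sum`, `out_pos`, `neg_count`,
#'   `gain`; empty when no bicluster was found.
#' @method tidy rarebic_bicluster
#' @export
tidy.rarebic_bicluster <- function(x, ...) {
  if (!x$found) {
    return(tibble(gene = character(0), in_sum = numeric(0),
                  out_pos = numeric(0), neg_count = integer(0),
                  gain = numeric(0)))
  }
  M <- expression_matrix(x$expression, normalized = TRUE)
  dplyr::arrange(gene_stats(M, cells = x$cells, kappa = x$kappa),
                 dplyr::desc(.data$gain))
}

#' Glance at a fitted bicluster
#'
#' @inheritParams tidy.rarebic_bicluster
#' @return A one-row tibble: `found`, `n_cells`, `n_genes`, `objective`,
#'   `negative_fraction`, `kappa`, `mu`, `n_evaluated`.
#' @method glance rarebic_bicluster
#' @export
glance.rarebic_bicluster <- function(x, ...) {
  tibble(found = x$found,
         n_cells = length(x$cells),
         n_genes = length(x$genes),
         objective = x$objective,
         negative_fraction = x$negative_fraction,
         kappa = x$kappa, mu = x$mu,
         n_evaluated = x$n_evaluated)
}

#' Tidy a top-k result
#'
#' @param x A `rarebic_topk`.
#' @param ... Unused.
#' @return A tibble with one row per bicluster: `rank`, `round`, `n_cells`,
#'   `n_genes`, `objective`, `negative_fraction`, and list-columns `cells`
#'   and `genes`.
#' @method tidy rarebic_topk
#' @export
tidy.rarebic_topk <- function(x, ...) {
  purrr::map_dfr(x$results, function(f) {
    tibble(rank = f$rank, round = f$round,
           n_cells = length(f$cells), n_genes = length(f$genes),
           objective = f$objective,
           negative_fraction = f$negative_fraction,
           cells = list(f$cells), genes = list(f$genes))
  })
}

#' Tidy / glance methods for controlled-experiment reports
#'
#' `tidy()` returns the per-run precision/recall/F1 table; `glance()` the
#' aggregate counts and means.
#'
#' @param x A `rarebic_eval`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy rarebic_eval
#' @export
tidy.rarebic_eval <- function(x, ...) x$per_run

#' @rdname tidy.rarebic_eval
#' @method glance rarebic_eval
#' @export
glance.rarebic_eval <- function(x, ...) {
  tibble(n_runs = x$n_runs,
         nb_subset = x$nb_subset,
         nb_exact = x$nb_exact,
         mean_precision = x$mean_precision,
         mean_recall = x$mean_recall,
         mean_f1 = x$mean_f1,
         k = x$k)
}
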