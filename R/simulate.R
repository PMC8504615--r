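#' Design of a planted-subpopulation experiment
#'
#' Describes a synthetic scRNA-seq count matrix made of an abundant
#' background population plus one or more small planted subpopulations, each
#' expressing its own dedicated set of marker genes. Counts are negative
#' binomial; dropout zeroes marker reads in the rare cells independently.
#' Background cells occasionally express a marker spuriously
#' (`background_rate`), and every gene carries sparse scattered background
#' expression (`noise_rate`) so that, after log-normalization, most entries
#' of the matrix are negative.
#'
#' Defaults emulate a deeply sequenced plate-based experiment: 50 cells of
#' which 5 (10%) form the rare subpopulation, 1000 candidate genes of which
#' 20 are dedicated markers with mean count 50.
#'
#' @param n_cells Total number of cells.
#' @param n_rare Rare cells per planted subpopulation (vector for several
#'   disjoint subpopulations). Each must be at least 5.
#' @param n_genes Total number of genes.
#' @param n_markers Marker genes per subpopulation (recycled along
#'   `n_rare`); marker sets are disjoint across subpopulations.
#' @param marker_mean Negative-binomial mean count of a marker in a rare
#'   cell (raw count scale).
#' @param background_rate Probability that a marker gene is spuriously
#'   expressed (at marker level) in a background cell.
#' @param dropout Probability that a marker read in a rare cell is zeroed.
#' @param nb_dispersion Negative-binomial `size` (dispersion) parameter.
#' @param noise_rate Probability that any gene is expressed in any cell as
#'   scattered background noise.
#' @param noise_mean Mean count of a background noise read.
#' @param seed Integer seed; generation is deterministic given the design.
#'
#' @return A list of class `planted_design`.
#' @export
planted_design <- function(n_cells = 50L, n_rare = 5L, n_genes = 1000L,
                           n_markers = 20L, marker_mean = 50,
                           background_rate = 0.01, dropout = 0.2,
                           nb_dispersion = 1, noise_rate = 0.005,
                           noise_mean = 20, seed = 1L) {
  n_rare <- as.integer(n_rare)
  n_markers <- as.integer(rep_len(n_markers, length(n_rare)))
  frac <- c(background_rate, dropout, noise_rate)
  if (any(frac < 0) || any(frac > 1)) {
    abort("`background_rate`, `dropout` and `noise_rate` must lie in [0, 1].",
          class = "rarebic_error_param")
  }
  if (any(n_rare < 5L)) {
    abort("Each planted subpopulation needs at least 5 cells.",
          class = "rarebic_error_param")
  }
  if (sum(n_rare) >= n_cells) {
    abort("`n_rare` must total fewer cells than `n_cells`.",
          class = "rarebic_error_param")
  }
  if (sum(n_markers) >= n_genes) {
    abort("`n_markers` must total fewer genes than `n_genes`.",
          class = "rarebic_error_param")
  }
  if (marker_mean <= 0 || nb_dispersion <= 0 || noise_mean <= 0) {
    abort("`marker_mean`, `noise_mean` and `nb_dispersion` must be positive.",
          class = "rarebic_error_param")
  }
  structure(
    list(n_cells = as.integer(n_cells), n_rare = n_rare,
         n_genes = as.integer(n_genes), n_markers = n_markers,
         marker_mean = marker_mean, background_rate = background_rate,
         dropout = dropout, nb_dispersion = nb_dispersion,
         noise_rate = noise_rate, noise_mean = noise_mean,
         seed = as.integer(seed)),
    class = "planted_design"
  )
}

#' Generate a planted-subpopulation count matrix
#'
#' Draws the raw count matrix described by a [planted_design()]. Rare-cell
#' and marker-gene positions are sampled uniformly, so the planted structure
#' is not tied to any corner of the matrix. The same design (including its
#' seed) always produces the identical matrix.
#'
#' @param design A [planted_design()].
#' @return A list: `matrix` (raw-count [expression_matrix()]), `rare_cells`
#'   (list of character vectors, one per subpopulation), `marker_genes`
#'   (list of character vectors, parallel to `rare_cells`).
#' @examples
#' sim <- generate_planted(planted_design(n_cells = 50, n_rare = 5, seed = 7))
#' length(sim$rare_cells[[1]])
#' @export
generate_planted <- function(design) {
  if (!inherits(design, "planted_design")) {
    abort("`design` must come from `planted_design()`.", class = "rarebic_error_param")
  }
  withr::local_seed(design$seed)
  G <- design$n_genes; C <- design$n_cells
  gene_names <- sprintf("g%04d", seq_len(G))
  cell_names <- sprintf("c%03d", seq_len(C))
  counts <- matrix(0, G, C, dimnames = list(gene_names, cell_names))

  # scattered background noise over the whole matrix
  noise_mask <- matrix(runif(G * C) < design$noise_rate, G, C)
  counts[noise_mask] <- rnbinom(sum(noise_mask), mu = design$noise_mean,
                                size = design$nb_dispersion)

  n_blocks <- length(design$n_rare)
  cell_pool <- sample.int(C)
  gene_pool <- sample.int(G)
  rare_cells <- vector("list", n_blocks)
  marker_genes <- vector("list", n_blocks)
  c_off <- 0L; g_off <- 0L
  for (b in seq_len(n_blocks)) {
    nr <- design$n_rare[b]; nm <- design$n_markers[b]
    rc <- sort(cell_pool[c_off + seq_len(nr)]); c_off <- c_off + nr
    mg <- sort(gene_pool[g_off + seq_len(nm)]); g_off <- g_off + nm
    # markers in their rare cells: NB counts thinned by dropout
    vals <- rnbinom(nm * nr, mu = design$marker_mean, size = design$nb_dispersion)
    vals[runif(nm * nr) < design$dropout] <- 0
    counts[mg, rc] <- vals
    # spurious marker expression in the remaining cells
    other <- setdiff(seq_len(C), rc)
    spur <- matrix(runif(nm * length(other)) < design$background_rate,
                   nm, length(other))
    block <- matrix(0, nm, length(other))
    block[spur] <- rnbinom(sum(spur), mu = design$marker_mean,
                           size = design$nb_dispersion)
    counts[mg, other] <- block
    rare_cells[[b]] <- cell_names[rc]
    marker_genes[[b]] <- gene_names[mg]
  }
  list(matrix = expression_matrix(counts, normalized = FALSE),
       rare_cells = rare_cells,
       marker_genes = marker_genes)
}

#' Precision, recall and F1 of a predicted cell set
#'
#' Precision is the share of predicted cells that belong to the true rare
#' subpopulation; recall is the share of the true subpopulation that was
#' predicted. An empty prediction scores (0, 0, 0) by convention.
#'
#' @param predicted Character vector of predicted cell names (may be empty).
#' @param truth Non-empty character vector of true rare-cell names.
#' @return A one-row tibble with `precision`, `recall`, `f1`.
#' @examples
#' precision_recall_f1(c("a", "b", "c", "d"), c("a", "b", "c", "e", "f"))
#' @export
precision_recall_f1 <- function(predicted, truth) {
  if (length(truth) == 0L) {
    abort("`truth` must be non-empty.", class = "rarebic_error_param")
  }
  if (length(predicted) == 0L) {
    return(tibble(precision = 0, recall = 0, f1 = 0))
  }
  tp <- length(intersect(predicted, truth))
  precision <- tp / length(unique(predicted))
  recall <- tp / length(unique(truth))
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(precision = precision, recall = recall, f1 = f1)
}

#' Controlled recovery experiment on planted data
#'
#' Repeats, `n_runs` times: generate a planted matrix (run `r` uses seed
#' `design$seed + r - 1`), log-normalize, search for the top-`k` biclusters,
#' and score the bicluster with the highest precision against the planted
#' labels (ties resolved by higher recall, then rank). The report aggregates
#' the number of runs at 100% precision (`nb_subset`), at 100% precision and
#' recall (`nb_exact`), and the mean precision/recall/F1.
#'
#' Only single-subpopulation designs are scored (the first planted block is
#' the truth).
#'
#' @param design A [planted_design()]; `design$seed` acts as the master seed.
#' @param params A [bicluster_params()].
#' @param n_runs Number of independent repetitions (>= 1).
#' @param k Top-k depth passed to [top_k()].
#' @return An object of class `rarebic_eval` with a `per_run` tibble and the
#'   aggregate counts and means.
#' @export
run_controlled_experiment <- function(design, params = bicluster_params(),
                                      n_runs = 10L, k = 1L) {
  if (n_runs < 1L) abort("`n_runs` must be >= 1.", class = "rarebic_error_param")
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    d <- design
    d$seed <- design$seed + r - 1L
    sim <- generate_planted(d)
    truth <- sim$rare_cells[[1L]]
    norm <- log_normalize(sim$matrix)
    fits <- top_k(norm, params, k = k)
    if (length(fits$results) == 0L) {
      runs[[r]] <- tibble(run = r, seed = d$seed, rank = NA_integer_,
                          precision = 0, recall = 0, f1 = 0)
      next
    }
    scored <- purrr::map_dfr(fits$results, function(f) {
      dplyr::mutate(precision_recall_f1(f$cells, truth), rank = f$rank)
    })
    best <- scored[order(-scored$precision, -scored$recall, scored$rank), ][1L, ]
    runs[[r]] <- tibble(run = r, seed = d$seed, rank = best$rank,
                        precision = best$precision, recall = best$recall,
                        f1 = best$f1)
  }
  per_run <- dplyr::bind_rows(runs)
  eps <- 1e-12
  structure(
    list(per_run = per_run,
         n_runs = n_runs,
         nb_subset = sum(per_run$precision >= 1 - eps),
         nb_exact = sum(per_run$precision >= 1 - eps & per_run$recall >= 1 - eps),
         mean_precision = mean(per_run$precision),
         mean_recall = mean(per_run$recall),
         mean_f1 = mean(per_run$f1),
         design = design, params = params, k = k),
    class = "rarebic_eval"
  )
}

#' @export
print.rarebic_eval <- function(x, ...) {
  cat(sprintf("<rarebic_eval> %d runs, top-%d strategy\n", x$n_runs, x$k))
  cat(sprintf("  runs with 100%% precision: %d; with 100%% precision and recall: %d\n",
              x$nb_subset, x$nb_exact))
  cat(sprintf("  mean precision %.3f, recall %.3f, F1 %.3f\n",
              x$mean_precision, x$mean_recall, x$mean_f1))
  invisible(x)
}
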