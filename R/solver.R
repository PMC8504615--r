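# construct the result object shared by all solvers
new_bicluster <- function(M, genes_idx, cells_idx, objective, kappa, mu,
                          n_evaluated = NA_integer_, trace = NULL,
                          method = "beam") {
  v <- unclass_expr(M)
  found <- length(genes_idx) > 0L && length(cells_idx) > 0L
  genes <- rownames(v)[genes_idx]
  cells <- colnames(v)[cells_idx]
  nf <- if (found) sum(v[genes_idx, cells_idx, drop = FALSE] < 0) /
    (length(genes_idx) * length(cells_idx)) else NA_real_
  structure(
    list(found = found,
         cells = cells,
         genes = genes,
         objective = if (found) objective else NA_real_,
         negative_fraction = nf,
         kappa = kappa, mu = mu,
         n_cells_total = ncol(v), n_genes_total = nrow(v),
         n_evaluated = n_evaluated,
         trace = trace,
         method = method,
         expression = if (found) v[genes_idx, , drop = FALSE] else NULL),
    class = "rarebic_bicluster"
  )
}

#' @export
print.rarebic_bicluster <- function(x, ...) {
  cat("<rarebic_bicluster>\n")
  if (!x$found) {
    cat("  no feasible bicluster found",
        sprintf("(kappa = %.4g, mu = %.3g)\n", x$kappa, x$mu))
    cat(sprintf("  %s candidate cell sets evaluated over %d cells x %d genes\n",
                format(x$n_evaluated), x$n_cells_total, x$n_genes_total))
    return(invisible(x))
  }
  cat(sprintf("  %d cells x %d genes, objective %.6g (kappa = %.4g, mu = %.3g)\n",
              length(x$cells), length(x$genes), x$objective, x$kappa, x$mu))
  cat(sprintf("  negative fraction inside bicluster: %.4g\n", x$negative_fraction))
  cat("  cells:", paste(head(x$cells, 10L), collapse = ", "),
      if (length(x$cells) > 10L) "..." else "", "\n")
  cat("  genes:", paste(head(x$genes, 10L), collapse = ", "),
      if (length(x$genes) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Evaluate one candidate cell set
#'
#' Runs the gene selection for a fixed cell set and, when a non-empty
#' feasible gene set exists, returns the corresponding bicluster. Candidate
#' cell sets for which every gene has non-positive gain, or for which no
#' positive-gain selection satisfies the negative-entry constraint, are
#' invalid and yield `NULL`.
#'
#' @inheritParams select_genes
#' @return A `rarebic_bicluster` or `NULL` (invalid candidate).
#' @export
evaluate_candidate <- function(M, cells, params = bicluster_params()) {
  m <- as_expr_matrix(M)
  v <- unclass_expr(m)
  jj <- resolve_idx(cells, colnames(v), "cell")
  if (length(jj) < 2L) {
    abort("A candidate needs at least 2 cells.", class = "rarebic_error_param")
  }
  kappa <- resolve_kappa(params, ncol(v))
  sub <- v[, jj, drop = FALSE]
  cs <- score_candidate(rowSums(sub) - kappa * (rowSums(pmax(v, 0)) - rowSums(pmax(sub, 0))),
                        rowSums(sub < 0), length(jj), params$mu)
  if (!cs$valid) return(NULL)
  new_bicluster(m, cs$genes, jj, cs$objective, kappa, params$mu,
                n_evaluated = 1L, method = "candidate")
}

#' Breadth-first beam search for the best bicluster
#'
#' Searches cell subsets level by level: all pairs of cells first, then
#' supersets obtained by adding one cell to the most promising sets of the
#' previous level. At each level only the `beam_width` best candidate sets
#' are retained (candidates carrying a feasible bicluster rank by objective;
#' the rest rank below them by the gain of their best singleton-feasible
#' gene). The gene set of each candidate is optimized by [select_genes()]'s
#' greedy rule, so every evaluated bicluster already satisfies the
#' negative-entry constraint. Duplicate cell sets reached through different
#' parents are evaluated once. The search stops when the frontier is empty,
#' when the level exceeds `max_cells`, or when the best feasible objective
#' has not improved for `patience` consecutive levels (counted only after a
#' first feasible bicluster has been found). The procedure is deterministic:
#' identical inputs give identical results.
#'
#' @param M Normalized (and typically prevalence-filtered) expression matrix.
#' @param params A [bicluster_params()] object.
#' @param verbose Print per-level frontier diagnostics.
#' @return A `rarebic_bicluster`; when nothing feasible exists the object has
#'   `found = FALSE` and carries the search trace for diagnosis.
#' @examples
#' fit <- beam_search(toy_expression_matrix(), bicluster_params(kappa = 1))
#' fit
#' @export
beam_search <- function(M, params = bicluster_params(), verbose = FALSE) {
  m <- as_expr_matrix(M)
  if (!is_normalized(m)) {
    abort("`beam_search()` expects a normalized matrix; run `log_normalize()` first.",
          class = "rarebic_error_input")
  }
  v <- unclass_expr(m)
  nG <- nrow(v); nC <- ncol(v)
  if (nC < 2L) abort("Need at least 2 cells.", class = "rarebic_error_input")
  kappa <- resolve_kappa(params, nC)
  mu <- params$mu
  bw <- as.integer(params$beam_width)
  max_c <- min(params$max_cells, nC)
  posm <- pmax(v, 0)
  total_pos_all <- rowSums(posm)
  # genes with no positive entry can never have positive gain nor carry a
  # feasible singleton; restrict the search to the rest
  active <- which(total_pos_all > 0)
  if (length(active) == 0L) {
    tr <- tibble(level = 2L, n_candidates = 0L, frontier_size = 0L,
                 best_objective = NA_real_)
    return(new_bicluster(m, integer(0), integer(0), NA_real_, kappa, mu,
                         n_evaluated = 0L, trace = tr))
  }
  va <- v[active, , drop = FALSE]
  # per-cell additive gain contribution: gain(J) = -kappa*total_pos + sum_j add[, j]
  addm <- va + kappa * pmax(va, 0)
  negm <- matrix(as.integer(va < 0), nrow(va), ncol(va))
  base_gain <- -kappa * total_pos_all[active]
  n_eval <- 0L
  best <- NULL
  trace <- list()

  record_best <- function(cells_idx, cs, level) {
    if (cs$valid && level >= params$min_cells &&
        (is.null(best) || cs$objective > best$objective)) {
      best <<- list(cells = cells_idx, genes = cs$genes, objective = cs$objective)
      TRUE
    } else FALSE
  }

  # ---- level 2: all cell pairs -------------------------------------------
  pairs <- combn(nC, 2L)
  nP <- ncol(pairs)
  p_valid <- logical(nP); p_score <- numeric(nP); p_score2 <- numeric(nP)
  improved <- FALSE
  for (p in seq_len(nP)) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    gains <- base_gain + addm[, a] + addm[, b]
    cs <- score_candidate(gains, negm[, a] + negm[, b], 2L, mu)
    n_eval <- n_eval + 1L
    p_valid[p] <- cs$valid; p_score[p] <- cs$score; p_score2[p] <- cs$score2
    if (record_best(pairs[, p], cs, 2L)) improved <- TRUE
  }
  keep <- order(-p_valid, -p_score, -p_score2, seq_len(nP))[seq_len(min(bw, nP))]
  keep <- keep[is.finite(p_score2[keep])]   # nothing to gain from hopeless sets
  frontier <- lapply(keep, function(p) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    list(cells = pairs[, p],
         gain = base_gain + addm[, a] + addm[, b],
         neg = negm[, a] + negm[, b])
  })
  level <- 2L
  stall <- 0L
  trace[[1L]] <- c(level = 2L, n_candidates = nP, frontier = length(frontier),
                   best = if (is.null(best)) NA_real_ else best$objective)
  if (verbose) {
    inform(sprintf("level 2: %d candidates, frontier %d, best %s",
                   nP, length(frontier),
                   if (is.null(best)) "none" else format(best$objective)))
  }
  # ---- deeper levels: expand supersets -----------------------------------
  while (length(frontier) > 0L && level < max_c) {
    improved <- FALSE
    cap <- length(frontier) * nC
    child_parent <- integer(cap); child_cell <- integer(cap)
    child_valid <- logical(cap); child_score <- numeric(cap); child_score2 <- numeric(cap)
    n_children <- 0L
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (fi in seq_along(frontier)) {
      f <- frontier[[fi]]
      for (cc in setdiff(seq_len(nC), f$cells)) {
        lt <- f$cells < cc   # frontier cells are kept sorted
        child_cells <- c(f$cells[lt], cc, f$cells[!lt])
        key <- paste(child_cells, collapse = ".")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        cs <- score_candidate(f$gain + addm[, cc], f$neg + negm[, cc],
                              level + 1L, mu)
        n_eval <- n_eval + 1L
        n_children <- n_children + 1L
        child_parent[n_children] <- fi; child_cell[n_children] <- cc
        child_valid[n_children] <- cs$valid
        child_score[n_children] <- cs$score
        child_score2[n_children] <- cs$score2
        if (record_best(child_cells, cs, level + 1L)) improved <- TRUE
      }
    }
    level <- level + 1L
    if (n_children == 0L) {
      frontier <- list()
    } else {
      idx <- seq_len(n_children)
      keep <- idx[order(-child_valid[idx], -child_score[idx],
                        -child_score2[idx], idx)][seq_len(min(bw, n_children))]
      keep <- keep[is.finite(child_score2[keep])]
      frontier <- lapply(keep, function(ci) {
        f <- frontier[[child_parent[ci]]]
        cc <- child_cell[ci]
        lt <- f$cells < cc
        list(cells = c(f$cells[lt], cc, f$cells[!lt]),
             gain = f$gain + addm[, cc],
             neg = f$neg + negm[, cc])
      })
    }
    trace[[length(trace) + 1L]] <-
      c(level = level, n_candidates = n_children, frontier = length(frontier),
        best = if (is.null(best)) NA_real_ else best$objective)
    if (verbose) {
      inform(sprintf("level %d: %d candidates, frontier %d, best %s",
                     level, n_children, length(frontier),
                     if (is.null(best)) "none" else format(best$objective)))
    }
    if (!is.null(best)) {
      stall <- if (improved) 0L else stall + 1L
      if (stall >= params$patience) break
    }
  }

  tr <- as_tibble(do.call(rbind, trace))
  names(tr) <- c("level", "n_candidates", "frontier_size", "best_objective")
  if (is.null(best)) {
    return(new_bicluster(m, integer(0), integer(0), NA_real_, kappa, mu,
                         n_evaluated = n_eval, trace = tr))
  }
  new_bicluster(m, active[best$genes], best$cells, best$objective, kappa, mu,
                n_evaluated = n_eval, trace = tr)
}

#' Exhaustive search over cell subsets (oracle)
#'
#' Enumerates every cell subset of size `min_cells` to `max_cells`, optimizes
#' the gene set for each, and returns the global optimum. Intended as an
#' independent check of [beam_search()] on small instances; refuses more
#' than 20 cells unless `force = TRUE`. Ties are broken in favour of fewer
#' cells, then lexicographic cell order.
#'
#' @inheritParams beam_search
#' @param exact_genes Use exact (enumerative) constrained gene selection for
#'   every candidate instead of the same greedy rule the beam search uses.
#'   Keep `FALSE` when comparing against [beam_search()].
#' @param force Override the 20-cell guard.
#' @return A `rarebic_bicluster` (with `found = FALSE` when nothing is
#'   feasible).
#' @export
exhaustive_search <- function(M, params = bicluster_params(),
                              exact_genes = FALSE, force = FALSE) {
  m <- as_expr_matrix(M)
  if (!is_normalized(m)) {
    abort("`exhaustive_search()` expects a normalized matrix.",
          class = "rarebic_error_input")
  }
  v <- unclass_expr(m)
  nC <- ncol(v)
  if (nC > 20L && !force) {
    abort(sprintf("Exhaustive search over %d cells would enumerate 2^%d subsets; use `force = TRUE` if you really mean it.",
                  nC, nC),
          class = "rarebic_error_guard")
  }
  kappa <- resolve_kappa(params, nC)
  mu <- params$mu
  posm <- pmax(v, 0)
  total_pos <- rowSums(posm)
  negm <- v < 0
  best <- NULL
  n_eval <- 0L
  max_c <- min(params$max_cells, nC)
  for (size in seq(params$min_cells, max_c)) {
    sets <- combn(nC, size, simplify = FALSE)
    for (jj in sets) {
      sub <- v[, jj, drop = FALSE]
      gains <- rowSums(sub) - kappa * (total_pos - rowSums(posm[, jj, drop = FALSE]))
      negc <- rowSums(negm[, jj, drop = FALSE])
      cs <- if (exact_genes) select_exact(gains, negc, size, mu)
            else score_candidate(gains, negc, size, mu)
      n_eval <- n_eval + 1L
      if (cs$valid && (is.null(best) || cs$objective > best$objective)) {
        best <- list(cells = jj, genes = cs$genes, objective = cs$objective)
      }
    }
  }
  if (is.null(best)) {
    return(new_bicluster(m, integer(0), integer(0), NA_real_, kappa, mu,
                         n_evaluated = n_eval, method = "exhaustive"))
  }
  new_bicluster(m, best$genes, best$cells, best$objective, kappa, mu,
                n_evaluated = n_eval, method = "exhaustive")
}

#' Top-k disjoint biclusters
#'
#' Runs the search, removes the cells of the solution from the matrix,
#' re-applies the gene prevalence filter on the remaining cells, and repeats,
#' up to `k` times or until no feasible bicluster (or too few cells) remains.
#' Returned cell sets are pairwise disjoint; gene sets may overlap. Each
#' round resolves `kappa = 100 / n_remaining_cells` when `kappa` is unset.
#'
#' @param M Normalized expression matrix (the prevalence filter is applied
#'   internally each round, so an unfiltered matrix is fine).
#' @inheritParams beam_search
#' @param k Maximum number of biclusters; shorter results are legal.
#' @return An object of class `rarebic_topk`: a list of `rarebic_bicluster`
#'   ordered by decreasing objective, with `rank` and `round` fields.
#' @export
top_k <- function(M, params = bicluster_params(), k = params$top_k,
                  verbose = FALSE) {
  m <- as_expr_matrix(M)
  if (!is_normalized(m)) {
    abort("`top_k()` expects a normalized matrix; run `log_normalize()` first.",
          class = "rarebic_error_input")
  }
  if (k < 1L) abort("`k` must be >= 1.", class = "rarebic_error_param")
  remaining <- colnames(m)
  results <- list()
  for (round in seq_len(k)) {
    if (length(remaining) < max(2L, params$min_cells)) break
    sub <- as_expr_matrix(unclass_expr(m)[, remaining, drop = FALSE],
                          normalized = TRUE)
    filt <- tryCatch(filter_genes(sub, params$max_prevalence),
                     rarebic_error_empty = function(e) NULL)
    if (is.null(filt)) break
    fit <- beam_search(filt, params, verbose = verbose)
    if (!fit$found) break
    fit$round <- round
    results[[round]] <- fit
    remaining <- setdiff(remaining, fit$cells)
  }
  ord <- order(-vapply(results, function(f) f$objective, numeric(1)))
  results <- results[ord]
  for (i in seq_along(results)) results[[i]]$rank <- i
  structure(list(results = results, params = params, k = k),
            class = "rarebic_topk")
}

#' @export
print.rarebic_topk <- function(x, ...) {
  cat(sprintf("<rarebic_topk> %d of %d requested bicluster(s)\n",
              length(x$results), x$k))
  for (f in x$results) {
    cat(sprintf("  #%d (round %d): %d cells x %d genes, objective %.6g\n",
                f$rank, f$round, length(f$cells), length(f$genes), f$objective))
  }
  invisible(x)
}
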