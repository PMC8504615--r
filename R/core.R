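#' Per-gene contribution statistics for a fixed cell set
#'
#' For each gene `i` and a fixed cell set `J`, computes the quantities that
#' drive the bicluster objective:
#' * `in_sum`: sum of the gene's values over the cells in `J`;
#' * `out_pos`: positive expression mass outside `J`,
#'   `sum_{k not in J} max(0, m_ik)`;
#' * `neg_count`: number of cells in `J` where the gene is negative
#'   (strictly below 0);
#' * `gain`: `in_sum - kappa * out_pos`, the gene's net contribution to the
#'   objective if it were selected.
#'
#' @param M Normalized expression matrix.
#' @param cells Cell identifiers (names or column indices) forming `J`.
#' @param genes Gene identifiers; default all genes.
#' @param kappa Out-of-cluster penalty weight; default `100 / ncol(M)`.
#'
#' @return A tibble with one row per gene: `gene`, `in_sum`, `out_pos`,
#'   `neg_count`, `gain`.
#' @examples
#' M <- expression_matrix(rbind(g1 = c(2, 1, -1, 3)), normalized = TRUE)
#' gene_stats(M, cells = c("c1", "c2"), kappa = 1)
#' @export
gene_stats <- function(M, cells, genes = NULL, kappa = NULL) {
  m <- as_expr_matrix(M)
  v <- unclass_expr(m)
  jj <- resolve_idx(cells, colnames(v), "cell")
  if (length(jj) == 0L) abort("`cells` must be non-empty.", class = "rarebic_error_param")
  ii <- if (is.null(genes)) seq_len(nrow(v)) else resolve_idx(genes, rownames(v), "gene")
  kappa <- kappa %||% (100 / ncol(v))
  sub <- v[ii, jj, drop = FALSE]
  in_sum <- rowSums(sub)
  in_pos <- rowSums(pmax(sub, 0))
  total_pos <- rowSums(pmax(v[ii, , drop = FALSE], 0))
  out_pos <- total_pos - in_pos
  neg_count <- as.integer(rowSums(sub < 0))
  tibble(gene = rownames(v)[ii],
         in_sum = unname(in_sum),
         out_pos = unname(out_pos),
         neg_count = unname(neg_count),
         gain = unname(in_sum - kappa * out_pos))
}

#' Bicluster objective value
#'
#' The penalized max-sum submatrix objective: the sum over selected genes of
#' their in-cluster expression minus `kappa` times their out-of-cluster
#' positive expression. Additive over genes; an empty gene set scores 0.
#'
#' @inheritParams gene_stats
#' @param genes Gene identifiers forming the selected set `I`.
#' @return A single number.
#' @export
bicluster_objective <- function(M, genes, cells, kappa = NULL) {
  if (length(genes) == 0L) return(0)
  sum(gene_stats(M, cells = cells, genes = genes, kappa = kappa)$gain)
}

#' Fraction of negative entries inside a bicluster
#'
#' `|{(i, j) : m_ij < 0}| / (|I| * |J|)` over the selected submatrix. Entries
#' exactly equal to 0 are not counted as negative. A bicluster is feasible
#' when this fraction is at most `mu` (boundary inclusive).
#'
#' @inheritParams bicluster_objective
#' @return A fraction in `[0, 1]`.
#' @export
negative_fraction <- function(M, genes, cells) {
  m <- as_expr_matrix(M)
  v <- unclass_expr(m)
  if (length(genes) == 0L || length(cells) == 0L) {
    abort("`genes` and `cells` must be non-empty to define a negative fraction.",
          class = "rarebic_error_param")
  }
  ii <- resolve_idx(genes, rownames(v), "gene")
  jj <- resolve_idx(cells, colnames(v), "cell")
  sub <- v[ii, jj, drop = FALSE]
  sum(sub < 0) / length(sub)
}

# ---- internal candidate scoring -------------------------------------------
#
# Given per-gene gains and in-cluster negative counts for a fixed cell set of
# size n_J, pick the gene set. Only strictly positive gains are eligible:
# zero-gain genes add nothing but consume the mu budget, negative-gain genes
# always lower the objective. With mu >= 1 the optimum is exactly
# {i : gain_i > 0} (the objective is separable over genes). With mu < 1 the
# heuristic keeps positive-gain genes sorted by ascending neg_count (ties:
# descending gain, then gene order) and returns the longest feasible prefix;
# prefix feasibility is monotone because the running mean of a sorted
# sequence is non-decreasing.
#
# Candidates without a feasible positive-gain selection are "invalid": they
# carry no bicluster, but the beam still needs to order them. Their score is
# the gain of the best gene that would be feasible on its own
# (neg_count <= mu * n_J), -Inf when no such gene exists; `score2` is the
# best unrestricted gain, used as a final tie-break.
score_candidate <- function(gains, neg_count, n_J, mu) {
  pos <- which(gains > 0)
  if (length(pos)) {
    # fast path: whole positive-gain set feasible (or unconstrained) -- the
    # longest feasible prefix is everything, no sorting needed
    if (mu >= 1 || sum(neg_count[pos]) <= mu * length(pos) * n_J) {
      obj <- sum(gains[pos])
      return(list(valid = TRUE, genes = pos, objective = obj,
                  score = obj, score2 = obj))
    }
    o <- pos[order(neg_count[pos], -gains[pos], pos)]
    ok <- cumsum(neg_count[o]) <= mu * seq_along(o) * n_J
    if (ok[[1L]]) {
      k <- max(which(ok))
      sel <- sort.int(o[seq_len(k)])
      obj <- sum(gains[sel])
      return(list(valid = TRUE, genes = sel, objective = obj,
                  score = obj, score2 = obj))
    }
  }
  feas <- neg_count <= mu * n_J
  score <- if (any(feas)) max(gains[feas]) else -Inf
  score2 <- if (length(gains)) max(gains) else -Inf
  list(valid = FALSE, genes = integer(0), objective = 0,
       score = score, score2 = score2)
}

# exact constrained gene selection by enumeration over positive-gain genes
# (subsets of other genes can never improve the objective; see select_genes)
select_exact <- function(gains, neg_count, n_J, mu) {
  pos <- which(gains > 0)
  p <- length(pos)
  if (p == 0L) return(list(valid = FALSE, genes = integer(0), objective = 0))
  if (mu >= 1) {
    return(list(valid = TRUE, genes = pos, objective = sum(gains[pos])))
  }
  if (p > 20L) {
    abort(sprintf("Exact gene selection is limited to 20 candidate genes (got %d).", p),
          class = "rarebic_error_guard")
  }
  g <- gains[pos]
  ng <- neg_count[pos]
  n_mask <- 2^p
  best_obj <- 0
  best_mask <- 0
  gsum <- numeric(n_mask)
  nsum <- numeric(n_mask)
  ksum <- integer(n_mask)
  for (mask in seq_len(n_mask - 1L)) {
    low <- bitwAnd(mask, -mask)
    idx <- 1L + as.integer(round(log2(low)))
    rest <- mask - low
    gsum[mask + 1L] <- gsum[rest + 1L] + g[idx]
    nsum[mask + 1L] <- nsum[rest + 1L] + ng[idx]
    ksum[mask + 1L] <- ksum[rest + 1L] + 1L
    if (nsum[mask + 1L] <= mu * ksum[mask + 1L] * n_J &&
        gsum[mask + 1L] > best_obj) {
      best_obj <- gsum[mask + 1L]
      best_mask <- mask
    }
  }
  if (best_mask == 0) return(list(valid = FALSE, genes = integer(0), objective = 0))
  sel <- pos[as.logical(bitwAnd(best_mask, 2^(seq_len(p) - 1L)))]
  list(valid = TRUE, genes = sel, objective = best_obj)
}

#' Optimal gene set for a fixed cell set
#'
#' With the cells fixed, the objective is additive over genes, so the
#' unconstrained (`mu = 1`) optimum is exactly the set of genes with strictly
#' positive gain, found in linear time. Under the negative-entry constraint
#' (`mu < 1`) the default is a greedy rule: positive-gain genes sorted by
#' ascending in-cluster negative count (ties broken by descending gain, then
#' input order), keeping the longest prefix whose negative fraction stays
#' within `mu`. `exact = TRUE` instead enumerates subsets of the positive-gain
#' genes (intended for small instances, at most 20 candidates) and returns
#' the constrained optimum.
#'
#' @inheritParams gene_stats
#' @param params A [bicluster_params()] object supplying `kappa`, `mu` and
#'   `min_cells`.
#' @param exact Use exhaustive subset enumeration instead of the greedy
#'   prefix rule.
#' @return A list with `genes` (character, possibly empty) and `objective`.
#'   An empty gene set means no gene has a feasible positive contribution;
#'   such a cell set does not support a bicluster.
#' @export
select_genes <- function(M, cells, params = bicluster_params(), exact = FALSE) {
  m <- as_expr_matrix(M)
  v <- unclass_expr(m)
  jj <- resolve_idx(cells, colnames(v), "cell")
  if (length(jj) < params$min_cells) {
    abort(sprintf("Need at least `min_cells` = %d cells (got %d).",
                  params$min_cells, length(jj)),
          class = "rarebic_error_param")
  }
  kappa <- resolve_kappa(params, ncol(v))
  sub <- v[, jj, drop = FALSE]
  in_sum <- rowSums(sub)
  in_pos <- rowSums(pmax(sub, 0))
  total_pos <- rowSums(pmax(v, 0))
  neg_count <- rowSums(sub < 0)
  gains <- in_sum - kappa * (total_pos - in_pos)
  res <- if (exact) {
    select_exact(gains, neg_count, length(jj), params$mu)
  } else {
    score_candidate(gains, neg_count, length(jj), params$mu)
  }
  list(genes = rownames(v)[res$genes], objective = res$objective)
}
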