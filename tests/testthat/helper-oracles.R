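# Independent brute-force oracles and fixture builders, written in plain
# base R on purpose: they must not share code paths with the package.

# per-gene gain/negative-count computed directly from the definition
oracle_gains <- function(m, jj, kappa) {
  sapply(seq_len(nrow(m)), function(i) {
    row <- m[i, ]
    in_sum <- sum(row[jj])
    out_pos <- sum(pmax(row[-jj], 0))
    in_sum - kappa * out_pos
  })
}

oracle_neg_counts <- function(m, jj) {
  sapply(seq_len(nrow(m)), function(i) sum(m[i, jj] < 0))
}

# exhaustive constrained gene selection over the positive-gain candidates
# (genes with non-positive gain can only lower the objective and are never
# part of the selection policy under test)
oracle_gene_select <- function(m, jj, kappa, mu) {
  gains <- oracle_gains(m, jj, kappa)
  negs <- oracle_neg_counts(m, jj)
  cand <- which(gains > 0)
  best_obj <- 0
  best_set <- integer(0)
  if (length(cand) > 0) {
    for (mask in 1:(2^length(cand) - 1)) {
      sel <- cand[as.logical(bitwAnd(mask, 2^(seq_along(cand) - 1)))]
      if (sum(negs[sel]) <= mu * length(sel) * length(jj) &&
          sum(gains[sel]) > best_obj) {
        best_obj <- sum(gains[sel])
        best_set <- sel
      }
    }
  }
  list(genes = sort(best_set), objective = best_obj)
}

# full search: every cell subset of size >= min_cells, oracle gene selection
oracle_best_bicluster <- function(m, kappa, mu, min_cells = 2) {
  nc <- ncol(m)
  best <- list(objective = 0, cells = integer(0), genes = integer(0))
  for (size in min_cells:nc) {
    combs <- combn(nc, size, simplify = FALSE)
    for (jj in combs) {
      sel <- oracle_gene_select(m, jj, kappa, mu)
      if (sel$objective > best$objective) {
        best <- list(objective = sel$objective, cells = jj, genes = sel$genes)
      }
    }
  }
  best
}

# independent feasibility check of a solver result
expect_feasible <- function(fit, M, mu, min_cells = 2) {
  expect_true(fit$found)
  expect_gte(length(fit$cells), min_cells)
  m <- as.matrix(unclass(M))
  sub <- m[fit$genes, fit$cells, drop = FALSE]
  expect_lte(sum(sub < 0) / length(sub), mu + 1e-12)
  # stored objective and negative fraction must agree with recomputation
  expect_equal(fit$negative_fraction, sum(sub < 0) / length(sub))
  expect_equal(fit$objective,
               bicluster_objective(M, fit$genes, fit$cells, kappa = fit$kappa),
               tolerance = 1e-10)
}

# small random signed matrix (mixed-sign, mostly sparse-in-positives)
random_signed_matrix <- function(seed, n_genes, n_cells, mean = -0.5, sd = 1.5) {
  set.seed(seed)
  expression_matrix(
    matrix(round(rnorm(n_genes * n_cells, mean, sd), 2), n_genes, n_cells),
    normalized = TRUE
  )
}

# planted block with distinct continuous values (unique optimum a.s.)
planted_block_matrix <- function(seed, n_genes = 20, n_cells = 10,
                                 block_genes = 1:5, block_cells = 1:3,
                                 level = 2) {
  set.seed(seed)
  m <- matrix(-1 - abs(rnorm(n_genes * n_cells, 0, 0.05)), n_genes, n_cells)
  m[block_genes, block_cells] <- level + rnorm(length(block_genes) * length(block_cells), 0, 0.05)
  expression_matrix(m, normalized = TRUE)
}
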