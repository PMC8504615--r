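#' Synthetic toy expression matrix
#'
#' A hand-built, synthetic 15-gene x 12-cell matrix of integer log-scale
#' expression values, illustrating what the constrained search looks for.
#' Three cells (`c3`, `c7`, `c10`) share five specifically expressed genes
#' (`g2`, `g5`, `g9`, `g12`, `g15`), with one dropout entry inside the block
#' (`g12` in `c7`) and a single out-of-cluster expression for three of the
#' markers. Gene `g3` is expressed in the block but also in four other
#' cells, so its out-of-cluster penalty excludes it from the solution. With
#' `kappa = 1`, `mu = 0.1` and the prevalence filter off, the optimal
#' bicluster is exactly those 3 cells and 5 genes (objective 23), which the
#' exhaustive oracle confirms.
#'
#' @return A normalized [expression_matrix()] (values are already on the
#'   signed log scale).
#' @examples
#' beam_search(toy_expression_matrix(),
#'             bicluster_params(kappa = 1, mu = 0.1))
#' @export
toy_expression_matrix <- function() {
  m <- matrix(-1, nrow = 15, ncol = 12,
              dimnames = list(paste0("g", 1:15), paste0("c", 1:12)))
  block_genes <- c("g2", "g5", "g9", "g12", "g15")
  block_cells <- c("c3", "c7", "c10")
  m[block_genes, block_cells] <- 2
  m["g12", "c7"] <- -1          # dropout inside the block
  m["g5", "c1"] <- 1            # single out-of-cluster expressions
  m["g9", "c12"] <- 2
  m["g15", "c6"] <- 1
  # g3: expressed in the block but broadly elsewhere -> penalized away
  m["g3", c(block_cells, "c2", "c5", "c8", "c12")] <- 2
  # unrelated scattered expression, including two cells (c2, c12) that look
  # attractive to an unpenalized max-sum criterion
  m["g4", c("c2", "c12")] <- 3
  m["g7", "c2"] <- 2; m["g7", "c5"] <- 1
  m["g10", "c12"] <- 2; m["g10", "c8"] <- 1
  m["g1", c("c1", "c4")] <- 1
  m["g6", c("c6", "c9")] <- 1
  m["g8", "c11"] <- 1
  m["g11", c("c4", "c8")] <- 1
  m["g13", "c5"] <- 2; m["g13", "c9"] <- 1
  m["g14", c("c1", "c11")] <- 1
  expression_matrix(m, normalized = TRUE)
}
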