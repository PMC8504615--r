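test_that("gene statistics match hand evaluation of the objective terms", {
  M <- expression_matrix(rbind(g1 = c(2, 1, -1, 3)), normalized = TRUE)
  st <- gene_stats(M, cells = c("c1", "c2"), kappa = 1)
  expect_equal(st$in_sum, 3)
  expect_equal(st$out_pos, 3)
  expect_equal(st$neg_count, 0L)
  expect_equal(st$gain, 0)

  # J = all cells: no out-of-cluster mass, gain = row sum
  st_all <- gene_stats(M, cells = colnames(M), kappa = 5)
  expect_equal(st_all$out_pos, 0)
  expect_equal(st_all$gain, 5)

  # kappa = 0: penalty vanishes
  st0 <- gene_stats(M, cells = c("c1", "c2"), kappa = 0)
  expect_equal(st0$gain, st0$in_sum)

  expect_error(gene_stats(M, cells = "nope"), class = "rarebic_error_lookup")
  expect_error(gene_stats(M, cells = "c1", genes = "gX"),
               class = "rarebic_error_lookup")
})

test_that("objective is the sum of gains, zero on the empty gene set", {
  M <- expression_matrix(rbind(g1 = c(1, 1, -2), g2 = c(2, -1, 1)),
                         normalized = TRUE)
  expect_equal(bicluster_objective(M, genes = character(0), cells = "c1"), 0)
  expect_equal(
    bicluster_objective(M, c("g1", "g2"), c("c1", "c2"), kappa = 0.5),
    2.5  # (2 - 0) + (1 - 0.5 * 1), hand evaluation
  )
  # linearity: scaling the matrix scales the objective
  M2 <- expression_matrix(unclass(M)[, ] * 3, normalized = TRUE)
  expect_equal(
    bicluster_objective(M2, c("g1", "g2"), c("c1", "c2"), kappa = 0.5),
    3 * 2.5
  )
})

test_that("negative fraction counts strict negatives only", {
  M <- expression_matrix(rbind(g1 = c(1, 0, 2), g2 = c(-1, 1, 1)),
                         normalized = TRUE)
  expect_equal(negative_fraction(M, c("g1", "g2"), c("c1", "c2", "c3")), 1 / 6)
  expect_equal(negative_fraction(M, "g1", c("c1", "c2")), 0)  # exact 0 not negative
  expect_error(negative_fraction(M, character(0), "c1"),
               class = "rarebic_error_param")
})

test_that("unconstrained gene selection is exactly the positive-gain set", {
  for (s in 1:20) {
    M <- random_signed_matrix(1000 + s, n_genes = 15, n_cells = 8)
    jj <- sort(sample(8, sample(2:5, 1)))
    kap <- runif(1, 0, 2)
    sel <- select_genes(M, cells = jj, bicluster_params(kappa = kap, mu = 1))
    gains <- oracle_gains(unclass(M)[, ], jj, kap)
    expect_setequal(sel$genes, rownames(M)[gains > 0])
    expect_equal(sel$objective, sum(gains[gains > 0]))
  }
})

test_that("zero- and negative-gain genes are never selected", {
  # gains 3, 0, -1 -> only the first gene
  m <- rbind(gA = c(3, 0, 0), gB = c(0, 0, 0), gC = c(-1, 0, 0))
  M <- expression_matrix(m, normalized = TRUE)
  sel <- select_genes(M, cells = colnames(M), bicluster_params(kappa = 1, mu = 1))
  expect_equal(sel$genes, "gA")
  # all gains negative -> empty set, objective 0
  Mneg <- expression_matrix(-abs(m) - 1, normalized = TRUE)
  sel2 <- select_genes(Mneg, cells = colnames(Mneg), bicluster_params(kappa = 1))
  expect_length(sel2$genes, 0)
  expect_equal(sel2$objective, 0)
})

test_that("selected gene set shrinks as kappa grows (mu = 1)", {
  M <- random_signed_matrix(99, n_genes = 25, n_cells = 10)
  jj <- 1:3
  prev <- NULL
  for (kap in c(0, 0.25, 0.5, 1, 2, 4, 8)) {
    sel <- select_genes(M, cells = jj, bicluster_params(kappa = kap, mu = 1))
    if (!is.null(prev)) expect_true(all(sel$genes %in% prev))
    prev <- sel$genes
  }
})

test_that("constrained selection respects the negative-entry budget", {
  # J of 2 cells, mu = 0.25; (gain, neg): gA (5,1), gB (4,0), gC (3,1)
  m <- rbind(gA = c(6, -1, 0), gB = c(2, 2, 0), gC = c(4, -1, 0))
  M <- expression_matrix(m, normalized = TRUE)
  p <- bicluster_params(kappa = 1, mu = 0.25)
  sel <- select_genes(M, cells = c("c1", "c2"), p)
  expect_setequal(sel$genes, c("gA", "gB"))
  expect_equal(sel$objective, 9)
  # exhaustive check over all 2^3 gene subsets agrees
  oracle <- oracle_gene_select(m, 1:2, kappa = 1, mu = 0.25)
  expect_equal(sel$objective, oracle$objective)
  # selecting all three genes would be infeasible: 2 negatives > 0.25 * 6
  expect_gt(negative_fraction(M, c("gA", "gB", "gC"), c("c1", "c2")), 0.25)
})

test_that("exact selection matches subset enumeration; heuristic never beats it", {
  gaps <- numeric(0)
  for (s in 1:25) {
    M <- random_signed_matrix(2000 + s, n_genes = 10, n_cells = 6)
    jj <- sort(sample(6, sample(2:4, 1)))
    kap <- runif(1, 0, 1.5)
    mu <- sample(c(0.1, 0.2, 0.34), 1)
    p <- bicluster_params(kappa = kap, mu = mu)
    exact <- select_genes(M, cells = jj, p, exact = TRUE)
    heur <- select_genes(M, cells = jj, p)
    oracle <- oracle_gene_select(unclass(M)[, ], jj, kap, mu)
    expect_equal(exact$objective, oracle$objective, tolerance = 1e-10)
    expect_lte(heur$objective, exact$objective + 1e-10)
    gaps <- c(gaps, exact$objective - heur$objective)
  }
  # report the heuristic-vs-exact gap for the record
  testthat::expect_gte(mean(gaps), -1e-10)
  message(sprintf("greedy-vs-exact gene selection: mean gap %.4f, max gap %.4f over 25 instances",
                  mean(gaps), max(gaps)))
})

test_that("selection requires at least min_cells cells", {
  M <- random_signed_matrix(3, 5, 5)
  expect_error(select_genes(M, cells = "c1", bicluster_params()),
               class = "rarebic_error_param")
})

test_that("parameter constructor validates its arguments", {
  expect_error(bicluster_params(kappa = -1), class = "rarebic_error_param")
  expect_error(bicluster_params(mu = 1.5), class = "rarebic_error_param")
  expect_error(bicluster_params(min_cells = 1), class = "rarebic_error_param")
  expect_error(bicluster_params(max_cells = 1), class = "rarebic_error_param")
  p <- bicluster_params()
  expect_null(p$kappa)      # resolved to 100/n_cells at solve time
  expect_equal(p$mu, 0.1)
})
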