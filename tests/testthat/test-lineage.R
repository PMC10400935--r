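test_that("cluster distance is symmetric, near zero for identical populations, and grows with separation", {
  grid <- test_grid()
  # two clusters drawn from the same parameters: merging loses ~nothing
  x <- sample_stationary(telegraph_params(1, 1, 20), 200, seed = 21)
  m <- expression_matrix(matrix(x, ncol = 1))
  lab <- rep(1:2, each = 100)
  d0 <- cluster_distance(m, lab, 1, 2, grid)
  expect_lt(abs(d0), 0.05)
  expect_equal(cluster_distance(m, lab, 2, 1, grid), d0)
  # separation sweep: theta_t ratios 2x, 5x, 20x
  dist_at <- function(ratio) {
    a <- sample_stationary(telegraph_params(1, 1, 4), 150, seed = 31)
    b <- sample_stationary(telegraph_params(1, 1, 4 * ratio), 150, seed = 32)
    mm <- expression_matrix(matrix(c(a, b), ncol = 1))
    cluster_distance(mm, rep(1:2, each = 150), 1, 2, grid)
  }
  ds <- sapply(c(2, 5, 20), dist_at)
  expect_true(all(diff(ds) > 0))
  expect_gt(ds[1], d0)
})

test_that("lineage graph adds ascending edges until connected and scales pseudotime", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 1; d[2, 3] <- d[3, 2] <- 2; d[1, 3] <- d[3, 1] <- 3
  gr <- build_lineage(d, root = 1)
  expect_equal(edge_set(gr$edges[, 1:2]), edge_set(rbind(c(1, 2), c(2, 3))))
  expect_true(igraph::is_connected(gr$igraph))
  expect_equal(gr$pseudotime, c(0, 0.5, 1))
  # unbalanced tree: every leaf reaches pseudotime 1, root stays 0
  d2 <- matrix(10, 5, 5); diag(d2) <- 0
  d2[1, 2] <- d2[2, 1] <- 1; d2[2, 3] <- d2[3, 2] <- 1.5
  d2[2, 4] <- d2[4, 2] <- 2; d2[4, 5] <- d2[5, 4] <- 1.2
  gr2 <- build_lineage(d2, root = 1)
  leaves <- setdiff(which(igraph::degree(gr2$igraph) == 1), 1)
  expect_true(all(gr2$pseudotime[leaves] == 1))
  expect_equal(gr2$pseudotime[1], 0)
  # max_edges extends beyond the spanning construction
  gr3 <- build_lineage(d, root = 1, max_edges = 3)
  expect_equal(nrow(gr3$edges), 3)
})

test_that("planted bifurcation topology is recovered from generated data", {
  grid <- test_grid()
  sc <- preset_scenarios(seed = 42)[["bifurcation-5"]]
  dat <- generate_lineage_data(sc)
  m <- normalize_counts(dat$expression, grid$m_max)
  cl <- burstscape:::make_clustering(burstscape:::storage_int(m),
                                     dat$truth$labels, grid)
  gr <- infer_lineage(m, cl, grid)   # root from capture times
  expect_equal(gr$root, 1L)
  expect_equal(edge_set(gr$edges[, 1:2]),
               edge_set(planted_edges[["bifurcation-5"]]))
})

test_that("cell placement interpolates endpoint likelihoods on each edge", {
  grid <- test_grid()
  sc <- lineage_scenario(cbind(1, 2), cells_per_cluster = 60, n_genes = 20,
                         seed = 3)
  dat <- generate_lineage_data(sc)
  m <- normalize_counts(dat$expression, grid$m_max)
  cl <- burstscape:::make_clustering(burstscape:::storage_int(m),
                                     dat$truth$labels, grid)
  gr <- infer_lineage(m, cl, grid)
  pc <- place_cells(m, cl, gr, grid)
  ll_mat <- burstscape:::loglik_matrix(m, cl$fit_idx, grid)
  # s = 0 reproduces the k1-endpoint log-likelihood exactly
  at0 <- pc$placements$s == 0
  expect_equal(pc$placements$log_lik[at0],
               ll_mat[cbind(which(at0), pc$placements$k1[at0])],
               tolerance = 1e-8)
  # the maximized value dominates both endpoints
  ends <- pmax(ll_mat[cbind(seq_len(nrow(m)), pc$placements$k1)],
               ll_mat[cbind(seq_len(nrow(m)), pc$placements$k2)])
  expect_true(all(pc$placements$log_lik >= ends - 1e-8))
  # per-gene NLL sums to the cell NLL at the optimum
  expect_equal(unname(rowSums(pc$gene_nll)), pc$placements$nll,
               tolerance = 1e-8)
  # coarse argmax matches a 10x finer s grid within one coarse step
  pc_fine <- place_cells(m, cl, gr, grid,
                         s_grid = seq(0, 1, length.out = 201))
  same_edge <- pc$placements$k1 == pc_fine$placements$k1 &
    pc$placements$k2 == pc_fine$placements$k2
  expect_true(all(same_edge))
  expect_true(all(abs(pc$placements$s - pc_fine$placements$s) <= 0.05 + 1e-9))
})

test_that("cell pseudotime interpolates cluster pseudotimes linearly", {
  gr <- build_lineage(matrix(c(0, 1, 1, 0), 2), root = 1)
  df <- data.frame(k1 = 1L, k2 = 2L, s = c(0, 0.3, 1))
  expect_equal(cell_pseudotime(df, gr), c(0, 0.3, 1))
  # monotone in s on a fixed edge
  s <- seq(0, 1, 0.1)
  pt <- cell_pseudotime(data.frame(k1 = 1L, k2 = 2L, s = s), gr)
  expect_true(all(diff(pt) > 0))
})

test_that("recovered pseudotime tracks the planted ordering on a linear lineage", {
  grid <- test_grid()
  sc <- preset_scenarios(seed = 42)[["linear-6"]]
  dat <- generate_lineage_data(sc)
  m <- normalize_counts(dat$expression, grid$m_max)
  cl <- burstscape:::make_clustering(burstscape:::storage_int(m),
                                     dat$truth$labels, grid)
  gr <- infer_lineage(m, cl, grid)
  pc <- place_cells(m, cl, gr, grid)
  sp <- cor(pc$placements$pseudotime, dat$truth$pseudotime,
            method = "spearman")
  expect_gte(sp, 0.8)
})
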