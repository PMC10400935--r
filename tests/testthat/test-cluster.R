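test_that("cell log-likelihood is the additive log product of gene probabilities", {
  grid <- test_grid()
  # single silent gene, zero count: probability one
  expect_equal(cell_log_likelihood(0L, list(telegraph_params(1, 1, 0)), grid),
               0)
  # additivity against gene_nll
  p1 <- telegraph_params(0.5, 0.5, 20); p2 <- telegraph_params(2, 1, 5)
  ll <- cell_log_likelihood(c(7L, 2L), list(p1, p2), grid)
  expect_equal(ll, -(gene_nll(7, p1, grid) + gene_nll(2, p2, grid)),
               tolerance = 1e-10)
  # grid-index route matches the naive product of cached PMF entries
  idx <- c(40L, 1500L, 900L)
  counts <- c(3L, 12L, 0L)
  naive <- log(prod(grid$pmf[cbind(idx, counts + 1L)]))
  expect_equal(cell_log_likelihood(counts, idx, grid), naive,
               tolerance = 1e-10)
  expect_lte(cell_log_likelihood(counts, idx, grid), 0)
  expect_error(cell_log_likelihood(c(1L, 2L), idx, grid), "per gene")
})

test_that("greedy clustering separates planted populations with monotone objective", {
  grid <- test_grid()
  # two populations contrasted on four genes (theta_t 1 vs 50); a single
  # gene cannot separate them at the likelihood optimum because the wide
  # high-theta_t distribution still produces low counts
  a <- sapply(1:4, function(g)
    sample_stationary(telegraph_params(1, 1, 1), 100, seed = g))
  b <- sapply(1:4, function(g)
    sample_stationary(telegraph_params(1, 1, 50), 100, seed = 10 + g))
  m <- expression_matrix(rbind(a, b))
  truth <- rep(1:2, each = 100)
  cl <- greedy_cluster(m, 2, grid, seed = 9)
  expect_equal(ari(cl$labels, truth), 1)
  expect_true(all(diff(cl$objective) >= -1e-8))
  # K = 1: pooled fit, label constant
  cl1 <- greedy_cluster(m, 1, grid, seed = 9)
  expect_true(all(cl1$labels == 1))
  pooled <- fit_mle_grid(as.integer(m[, 1]), grid)
  expect_equal(unname(cl1$fit_idx[1, 1]), pooled$index)
  # total log-likelihood consistency with per-cell values
  expect_equal(cl$total_log_likelihood, sum(cl$cell_log_lik),
               tolerance = 1e-8)
  expect_error(greedy_cluster(m, 300, grid, seed = 1), "more clusters")
})

test_that("consensus counts co-assignments symmetrically", {
  grid <- test_grid()
  set.seed(10)
  m <- expression_matrix(matrix(rpois(40 * 3, 5), 40, 3))
  cons <- consensus(m, 2, grid, n_runs = 1, seed = 4)
  expect_true(all(cons$counts %in% c(0L, 1L)))
  expect_true(all(diag(cons$counts) == 1))
  cons5 <- consensus(m, 2, grid, n_runs = 5, seed = 4)
  expect_identical(cons5$counts, t(cons5$counts))
  expect_true(all(diag(cons5$counts) == 5))
  expect_true(all(cons5$counts >= 0 & cons5$counts <= 5))
})

test_that("k-medoids finalization recovers planted consensus blocks", {
  grid <- test_grid()
  n <- 30; blocks <- rep(1:3, each = 10)
  cm <- outer(blocks, blocks, "==") * 10L
  cons <- structure(list(counts = cm, n_runs = 10),
                    class = "consensus_matrix")
  set.seed(6)
  counts <- expression_matrix(matrix(rpois(n * 4, 6), n, 4))
  fin <- finalize_kmedoids(cons, 3, counts, grid)
  expect_equal(ari(fin$labels, blocks), 1)
  # K = N: every cell its own cluster
  finN <- finalize_kmedoids(cons, n, counts, grid)
  expect_equal(sort(unique(unname(finN$labels))), 1:n)
  # permutation equivariance
  perm <- sample(n)
  cons_p <- structure(list(counts = cm[perm, perm], n_runs = 10),
                      class = "consensus_matrix")
  fin_p <- finalize_kmedoids(cons_p, 3, counts[perm, , drop = FALSE], grid)
  expect_equal(ari(fin_p$labels, blocks[perm]), 1)
  # degenerate all-identical consensus warns
  cons_d <- structure(list(counts = matrix(10L, 10, 10), n_runs = 10),
                      class = "consensus_matrix")
  expect_warning(
    finalize_kmedoids(cons_d, 2, counts[1:10, , drop = FALSE], grid),
    "degenerate")
})

test_that("eigengap heuristic counts planted blocks", {
  block_consensus <- function(sizes, n_runs = 10) {
    b <- rep(seq_along(sizes), sizes)
    structure(list(counts = outer(b, b, "==") * n_runs, n_runs = n_runs),
              class = "consensus_matrix")
  }
  expect_equal(eigengap_k(block_consensus(c(10, 10, 10)), k_max = 6), 3L)
  expect_equal(eigengap_k(block_consensus(c(12, 8)), k_max = 5), 2L)
  expect_equal(eigengap_k(block_consensus(c(5, 5, 5, 5)), k_max = 8), 4L)
  # all-ones consensus: degenerate, documented convention K = 2
  ones <- structure(list(counts = matrix(10L, 12, 12), n_runs = 10),
                    class = "consensus_matrix")
  expect_warning(k <- eigengap_k(ones, 5), "eigengap")
  expect_equal(k, 2L)
})
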