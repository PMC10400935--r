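# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Desk-scale fitting grid used throughout the synthetic analyses: axes
# bounded to the bursty regime covering the generator's kinetics (see the
# methods vignette for the rationale).
test_grid <- function() {
  if (is.null(.fixture_env$grid))
    .fixture_env$grid <- param_grid(
      theta_on = burstscape:::lseq(0.01, 10, 12),
      theta_off = burstscape:::lseq(0.1, 100, 12),
      theta_t = burstscape:::lseq(0.1, 300, 18),
      m_max = 150)
  .fixture_env$grid
}

analysis_config <- function(k = NA, n_runs = 8, seed = 42) {
  list(seed = seed,
       grid.theta_on_min = 0.01, grid.theta_on_max = 10, grid.theta_on_n = 12,
       grid.theta_off_min = 0.1, grid.theta_off_max = 100,
       grid.theta_off_n = 12,
       grid.theta_t_min = 0.1, grid.theta_t_max = 300, grid.theta_t_n = 18,
       grid.m_max = 150,
       cluster.k = k, cluster.n_runs = n_runs)
}

# Stationary Poisson-Beta probability by the confluent-hypergeometric
# series (Kummer-transformed so all terms are positive): an oracle fully
# independent of the quadrature implementation.
pb_pmf_series <- function(theta_on, theta_off, theta_t, m_max) {
  a <- theta_on; b <- theta_off
  sapply(0:m_max, function(m) {
    c1 <- a + b + m
    lpre <- -theta_t + m * log(theta_t) - lgamma(m + 1) +
      lbeta(a + m, b) - lbeta(a, b)
    term <- 1; s <- 1; j <- 0
    while (j < 1e5) {
      term <- term * (b + j) * theta_t / ((c1 + j) * (j + 1))
      s <- s + term
      j <- j + 1
      if (term < s * 1e-17) break
    }
    exp(lpre) * s
  })
}

edge_set <- function(m) {
  m <- t(apply(unname(as.matrix(m)), 1, sort))
  storage.mode(m) <- "integer"
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

planted_edges <- list(
  "linear-4" = cbind(1:3, 2:4),
  "linear-6" = cbind(1:5, 2:6),
  "bifurcation-5" = rbind(c(1, 2), c(2, 3), c(3, 4), c(3, 5)),
  "two-bifurcation-7" = rbind(c(1, 2), c(2, 3), c(2, 4), c(4, 5),
                              c(5, 6), c(5, 7)))

# Adjusted Rand index (Hubert & Arabie) for label agreement.
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  choose2 <- function(x) sum(choose(x, 2))
  sidx <- choose2(tab)
  sa <- choose2(rowSums(tab)); sb <- choose2(colSums(tab))
  expected <- sa * sb / choose(sum(tab), 2)
  (sidx - expected) / ((sa + sb) / 2 - expected)
}
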