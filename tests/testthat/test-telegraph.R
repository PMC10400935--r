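test_that("stationary PMF matches its closed-form limits", {
  # no transcription: all mass at zero
  p0 <- stationary_pmf(telegraph_params(1, 1, 0), m_max = 5)
  expect_equal(p0, c(1, 0, 0, 0, 0, 0))
  # always-ON limit: Poisson birth-death with rate theta_t
  p <- stationary_pmf(telegraph_params(50, 1e-6, 5), m_max = 40)
  expect_lt(max(abs(p - dpois(0:40, 5))), 1e-4)
  # analytic mean theta_t * theta_on / (theta_on + theta_off)
  for (pars in list(c(0.5, 0.5, 20), c(2, 0.7, 35), c(0.2, 3, 50))) {
    tp <- telegraph_params(pars[1], pars[2], pars[3])
    pmf <- stationary_pmf(tp, m_max = 150)
    mu <- pars[3] * pars[1] / (pars[1] + pars[2])
    expect_lt(abs(sum(0:150 * pmf) - mu) / mu, 1e-4)
  }
})

test_that("quadrature PMF agrees with the hypergeometric series", {
  for (pars in list(c(0.5, 0.5, 20), c(2, 5, 40), c(0.1, 0.8, 8))) {
    tp <- telegraph_params(pars[1], pars[2], pars[3])
    p_quad <- stationary_pmf(tp, m_max = 80)
    p_ser <- pb_pmf_series(pars[1], pars[2], pars[3], 80)
    expect_lt(max(abs(p_quad - p_ser)), 1e-8)
  }
})

test_that("stationary PMF matches Monte-Carlo and Gillespie oracles", {
  tp <- telegraph_params(0.5, 0.5, 20)
  pmf <- stationary_pmf(tp, m_max = 100)
  x <- sample_stationary(tp, 1e6, seed = 101)
  emp <- tabulate(x + 1, nbins = 101) / 1e6
  expect_lt(0.5 * sum(abs(emp - pmf)), 0.005)
  # ten randomized parameter sets against the exact mixture sampler
  set.seed(7)
  for (i in 1:10) {
    a <- 10^runif(1, -0.7, 0.7); b <- 10^runif(1, -0.7, 0.7)
    tt <- 10^runif(1, 0.5, 1.5)
    tp <- telegraph_params(a, b, tt)
    pmf <- stationary_pmf(tp, m_max = 120)
    x <- sample_stationary(tp, 1e6, seed = 1000 + i)
    emp <- tabulate(x + 1, nbins = 121) / 1e6
    expect_lt(0.5 * sum(abs(emp - pmf)), 0.005)
  }
  # stochastic simulation of the full reaction network
  for (pars in list(c(1, 1, 10), c(0.5, 2, 25), c(3, 0.5, 15))) {
    tp <- telegraph_params(pars[1], pars[2], pars[3])
    pmf <- stationary_pmf(tp, m_max = 100)
    set.seed(11)
    y <- burstscape:::.gillespie_counts(pars[1], pars[2], pars[3],
                                        n_cells = 1e5, t_end = 15)
    emp <- tabulate(pmin(y, 100) + 1, nbins = 101) / 1e5
    expect_lt(0.5 * sum(abs(emp - pmf)), 0.01)
  }
})

test_that("stationary sampler is deterministic with the analytic mean", {
  tp <- telegraph_params(1, 1, 20)
  x1 <- sample_stationary(tp, 1e5, seed = 5)
  x2 <- sample_stationary(tp, 1e5, seed = 5)
  expect_identical(x1, x2)
  # mean 10 with SE from the Poisson-Beta variance
  v <- var(x1)
  expect_lt(abs(mean(x1) - 10), 3 * sqrt(v / 1e5))
  expect_identical(sample_stationary(telegraph_params(1, 1, 0), 100, 1),
                   rep(0L, 100))
})

test_that("PMF truncation error handling follows the tail-mass contract", {
  expect_error(stationary_pmf(telegraph_params(50, 0.01, 150), m_max = 40),
               "m_max")
  expect_error(telegraph_params(Inf, 1, 1), "finite")
  expect_error(telegraph_params(0, 1, 1), "positive")
})

test_that("grid PMF cache is normalized with strictly increasing axes", {
  grid <- test_grid()
  sums <- rowSums(grid$pmf)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(grid$pmf >= 0))
  expect_true(all(diff(grid$theta_on) > 0))
  expect_true(all(diff(grid$theta_t) > 0))
  expect_error(param_grid(theta_on = c(1, 1, 2)), "increasing")
})

test_that("gene_nll is the negative log stationary probability", {
  grid <- test_grid()
  tp <- telegraph_params(0.5, 0.5, 20)
  pmf <- stationary_pmf(tp, grid$m_max, grid$n_nodes)
  counts <- c(0, 3, 17, 60)
  expect_equal(gene_nll(counts, tp, grid), -log(pmf[counts + 1]),
               tolerance = 1e-10)
  # zero count under a silent gene costs nothing
  expect_equal(gene_nll(0, telegraph_params(1, 1, 0), grid), 0)
  # the mode minimizes the NLL
  mode <- which.max(pmf) - 1
  nlls <- gene_nll(0:grid$m_max, tp, grid)
  expect_equal(which.min(nlls) - 1, mode)
  expect_error(gene_nll(grid$m_max + 1, tp, grid), "range")
})

test_that("grid MLE equals exhaustive search and recovers planted points", {
  grid <- test_grid()
  # naive oracle: loop over all grid rows, sum log probabilities
  set.seed(3)
  counts <- sample_stationary(telegraph_params(0.6, 2, 30), 400, seed = 33)
  naive <- sapply(seq_len(nrow(grid$points)), function(i)
    sum(log(pmax(grid$pmf[i, counts + 1], 1e-300))))
  fit <- fit_mle_grid(counts, grid)
  expect_equal(fit$index, which.max(naive))
  expect_equal(fit$log_lik, max(naive), tolerance = 1e-8)
  # draws from an exact grid point: burst size recovered within a step
  true <- grid_params(grid, 1500)
  counts <- sample_stationary(true, 1000, seed = 44)
  fit <- fit_mle_grid(counts, grid)
  step <- max(diff(log(grid$theta_t)), diff(log(grid$theta_off)))
  expect_lt(abs(log(burst_size(fit$params)) - log(burst_size(true))),
            2 * step + 1e-9)
  # all-zero counts: P(0) at the fit is the global maximum
  fit0 <- fit_mle_grid(rep(0L, 50), grid)
  expect_equal(grid$pmf[fit0$index, 1], max(grid$pmf[, 1]), tolerance = 1e-12)
  expect_error(fit_mle_grid(integer(0), grid), "no counts")
})

test_that("burst size and frequency follow the defining relations", {
  p <- telegraph_params(2, 10, 100)
  expect_equal(burst_size(p), 10)
  expect_equal(burst_frequency(p), 2)
  p2 <- telegraph_params(2, 20, 100)  # doubling theta_off halves S
  expect_equal(burst_size(p2), burst_size(p) / 2)
  expect_equal(burst_frequency(p2), burst_frequency(p))
  p3 <- telegraph_params(0.74, 1, 1)
  expect_equal(burst_frequency(p3), 0.74)
  expect_equal(burst_size(p3), 1)
})
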