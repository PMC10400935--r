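#' Parameters of the two-state (telegraph) transcription model
#'
#' The telegraph model describes a promoter that switches between an OFF
#' and an ON state with rates `theta_on` (activation) and `theta_off`
#' (inactivation), transcribes at rate `theta_t` while ON, and whose mRNA
#' degrades at rate `theta_d`. All rates are normalized by the mRNA
#' degradation rate, so `theta_d` is fixed at 1 and the remaining rates are
#' expressed per mRNA lifetime.
#'
#' @param theta_on Promoter activation rate (> 0).
#' @param theta_off Promoter inactivation rate (> 0).
#' @param theta_t Transcription rate while ON (>= 0).
#' @return An object of class `telegraph_params`.
#' @examples
#' telegraph_params(theta_on = 2, theta_off = 10, theta_t = 100)
#' @export
telegraph_params <- function(theta_on, theta_off, theta_t) {
  vals <- c(theta_on = theta_on, theta_off = theta_off, theta_t = theta_t)
  if (any(!is.finite(vals)))
    stop("telegraph parameters must be finite", call. = FALSE)
  if (theta_on <= 0 || theta_off <= 0)
    stop("theta_on and theta_off must be positive", call. = FALSE)
  if (theta_t < 0)
    stop("theta_t must be non-negative", call. = FALSE)
  structure(list(theta_on = theta_on, theta_off = theta_off,
                 theta_t = theta_t, theta_d = 1),
            class = "telegraph_params")
}

#' @export
print.telegraph_params <- function(x, ...) {
  cat(sprintf(
    "telegraph model: theta_on = %g, theta_off = %g, theta_t = %g (theta_d = 1)\n",
    x$theta_on, x$theta_off, x$theta_t))
  cat(sprintf("  burst size S = %g, burst frequency F = %g\n",
              burst_size(x), burst_frequency(x)))
  invisible(x)
}

#' Transcriptional burst size and frequency
#'
#' Burst size is the mean number of transcripts produced per ON episode,
#' `S = theta_t / theta_off`; burst frequency is the rate of ON episodes,
#' `F = theta_on` (both per mRNA lifetime).
#'
#' @param params A [telegraph_params()] object.
#' @return A single number.
#' @examples
#' p <- telegraph_params(2, 10, 100)
#' burst_size(p)       # 10
#' burst_frequency(p)  # 2
#' @export
burst_size <- function(params) {
  stopifnot(inherits(params, "telegraph_params"))
  if (params$theta_off == 0)
    stop("burst size undefined for theta_off = 0", call. = FALSE)
  params$theta_t / params$theta_off
}

#' @rdname burst_size
#' @export
burst_frequency <- function(params) {
  stopifnot(inherits(params, "telegraph_params"))
  params$theta_on
}

# Gauss-Jacobi quadrature on [-1, 1] with weight (1-x)^alpha (1+x)^beta,
# by Golub-Welsch on the symmetric tridiagonal Jacobi matrix. Weights are
# returned normalized to sum 1 (the zeroth moment cancels against the Beta
# normalizing constant when averaging over a Beta density).
gauss_jacobi <- function(n, alpha, beta) {
  stopifnot(n >= 1, alpha > -1, beta > -1)
  ab <- alpha + beta
  a <- numeric(n)
  a[1] <- (beta - alpha) / (ab + 2)
  if (n > 1) {
    k <- seq_len(n - 1)
    a[-1] <- (beta^2 - alpha^2) / ((2 * k + ab) * (2 * k + ab + 2))
  }
  if (n == 1) return(list(nodes = a, weights = 1))
  b <- numeric(n - 1)
  b[1] <- 4 * (1 + alpha) * (1 + beta) / ((2 + ab)^2 * (3 + ab))
  if (n > 2) {
    k <- 2:(n - 1)
    b[k] <- 4 * k * (k + alpha) * (k + beta) * (k + ab) /
      ((2 * k + ab)^2 * (2 * k + ab + 1) * (2 * k + ab - 1))
  }
  J <- matrix(0, n, n)
  diag(J) <- a
  off <- sqrt(b)
  J[cbind(seq_len(n - 1), 2:n)] <- off
  J[cbind(2:n, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  w <- e$vectors[1, ord]^2
  list(nodes = e$values[ord], weights = w / sum(w))
}

# Quadrature nodes on the Beta(theta_on, theta_off) density: p in (0, 1)
# with weights summing to 1, so E[f(p)] ~ sum(w * f(p)).
beta_nodes <- function(theta_on, theta_off, n_nodes) {
  gq <- gauss_jacobi(n_nodes, alpha = theta_off - 1, beta = theta_on - 1)
  list(p = (gq$nodes + 1) / 2, w = gq$weights)
}

#' Stationary mRNA count distribution of the telegraph model
#'
#' At stationarity the mRNA copy number follows a Poisson-Beta mixture:
#' `m ~ Poisson(theta_t * p)` with `p ~ Beta(theta_on, theta_off)`. The
#' mixture is evaluated by fixed-node Gauss-Jacobi quadrature over the Beta
#' density, which remains accurate for large `theta_t` where series
#' evaluations cancel catastrophically.
#'
#' @param params A [telegraph_params()] object.
#' @param m_max Largest count in the support of the returned vector.
#' @param n_nodes Number of quadrature nodes.
#' @return Numeric vector of probabilities over counts `0:m_max`. If the
#'   truncated tail mass exceeds 1e-3 an error asks for a larger `m_max`;
#'   the vector is renormalized only when the tail mass is below 1e-6.
#' @examples
#' p <- stationary_pmf(telegraph_params(0.5, 0.5, 20), m_max = 100)
#' sum(p)
#' @export
stationary_pmf <- function(params, m_max, n_nodes = 512) {
  stopifnot(inherits(params, "telegraph_params"), m_max >= 1)
  if (params$theta_t == 0) {
    pmf <- c(1, numeric(m_max))
  } else {
    nd <- beta_nodes(params$theta_on, params$theta_off, n_nodes)
    pmf <- .pb_pmf_quad(params$theta_t * nd$p, nd$w, as.integer(m_max))
  }
  s <- sum(pmf)
  if (1 - s > 1e-3)
    stop(sprintf(
      "tail mass %.3g beyond m_max = %d exceeds 1e-3; increase m_max",
      1 - s, m_max), call. = FALSE)
  if (abs(1 - s) < 1e-6) pmf <- pmf / s
  pmf
}

#' Draw counts from the stationary telegraph distribution
#'
#' Exact sampling through the mixture representation: `p ~ Beta(theta_on,
#' theta_off)`, then `m ~ Poisson(theta_t * p)`.
#'
#' @param params A [telegraph_params()] object.
#' @param n_cells Number of independent draws.
#' @param seed Integer seed; identical seeds give identical draws.
#' @return Integer vector of length `n_cells`.
#' @export
sample_stationary <- function(params, n_cells, seed) {
  stopifnot(inherits(params, "telegraph_params"), n_cells >= 1)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(seed)
  p <- stats::rbeta(n_cells, params$theta_on, params$theta_off)
  as.integer(stats::rpois(n_cells, params$theta_t * p))
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Log-spaced axis helper.
lseq <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

#' Discretized fitting grid for the telegraph model
#'
#' Builds the log-spaced (theta_on, theta_off, theta_t) grid over which
#' maximum-likelihood fits are searched, precomputing and caching the
#' stationary PMF at every grid point. Grid rows are ordered
#' lexicographically by (theta_t, theta_off, theta_on), which fixes the
#' deterministic tie-break used by [fit_mle_grid()]. Cached PMFs are
#' renormalized to sum exactly to 1 over `0:m_max` so that likelihoods of
#' different grid points are comparable on the truncated support.
#'
#' @param theta_on,theta_off,theta_t Strictly increasing axis values; the
#'   defaults are 20 log-spaced points in `[1e-2, 1e2]` for the switching
#'   rates and 25 log-spaced points in `[0.1, 2 * m_max]` for the
#'   transcription rate.
#' @param m_max Largest supported count (counts must be normalized to at
#'   most this value before fitting).
#' @param n_nodes Quadrature nodes per PMF.
#' @return An object of class `param_grid` with the axes, the expanded
#'   `points` table, and `pmf` / `log_pmf` caches (one row per grid point,
#'   columns = counts `0:m_max`).
#' @export
param_grid <- function(theta_on = lseq(1e-2, 1e2, 20),
                       theta_off = lseq(1e-2, 1e2, 20),
                       theta_t = NULL,
                       m_max = 200,
                       n_nodes = 512) {
  if (is.null(theta_t)) theta_t <- lseq(0.1, 2 * m_max, 25)
  for (ax in list(theta_on, theta_off, theta_t))
    if (any(diff(ax) <= 0) || any(!is.finite(ax)) || any(ax <= 0))
      stop("grid axes must be finite, positive and strictly increasing",
           call. = FALSE)
  n_on <- length(theta_on); n_off <- length(theta_off); n_t <- length(theta_t)
  points <- expand.grid(theta_on = theta_on, theta_off = theta_off,
                        theta_t = theta_t, KEEP.OUT.ATTRS = FALSE)
  np <- nrow(points)
  pmf <- matrix(0, np, m_max + 1)
  for (i_off in seq_len(n_off)) {
    for (i_on in seq_len(n_on)) {
      nd <- beta_nodes(theta_on[i_on], theta_off[i_off], n_nodes)
      lam <- outer(theta_t, nd$p)
      rows <- i_on + n_on * (i_off - 1) + n_on * n_off * (seq_len(n_t) - 1)
      pmf[rows, ] <- .pb_pmf_quad_batch(lam, nd$w, as.integer(m_max))
    }
  }
  pmf[pmf < 0] <- 0
  pmf <- pmf / rowSums(pmf)
  structure(list(theta_on = theta_on, theta_off = theta_off,
                 theta_t = theta_t, m_max = as.integer(m_max),
                 n_nodes = as.integer(n_nodes),
                 points = points, pmf = pmf,
                 log_pmf = log(pmax(pmf, 1e-300))),
            class = "param_grid")
}

#' @export
print.param_grid <- function(x, ...) {
  cat(sprintf(
    "telegraph fitting grid: %d x %d x %d points (theta_on x theta_off x theta_t), m_max = %d\n",
    length(x$theta_on), length(x$theta_off), length(x$theta_t), x$m_max))
  invisible(x)
}

grid_params <- function(grid, index) {
  telegraph_params(grid$points$theta_on[index],
                   grid$points$theta_off[index],
                   grid$points$theta_t[index])
}

#' Per-gene negative log-likelihood of a count
#'
#' `-log P(count)` under the stationary telegraph distribution; the
#' per-gene summand of a cell's transcriptional uncertainty.
#'
#' @param count Integer count(s) in `0:m_max`.
#' @param params A [telegraph_params()] object.
#' @param grid A [param_grid()] (supplies `m_max` and quadrature size).
#' @return Non-negative numeric vector, one value per count.
#' @export
gene_nll <- function(count, params, grid) {
  stopifnot(inherits(grid, "param_grid"))
  if (any(count < 0) || any(count > grid$m_max))
    stop(sprintf("count outside supported range 0..%d", grid$m_max),
         call. = FALSE)
  pmf <- stationary_pmf(params, grid$m_max, grid$n_nodes)
  -log(pmax(pmf[count + 1], 1e-300))
}

#' Grid maximum-likelihood fit of telegraph parameters
#'
#' Scans every cached grid point and returns the one maximizing the total
#' log-likelihood of the observed counts. Ties are broken by the first
#' maximizing row, i.e. the smallest (theta_t, theta_off, theta_on) in
#' lexicographic order.
#'
#' @param counts Integer vector of counts within `0:m_max`.
#' @param grid A [param_grid()].
#' @return List with `params` (a [telegraph_params()]), `log_lik`, and the
#'   grid row `index`.
#' @export
fit_mle_grid <- function(counts, grid) {
  stopifnot(inherits(grid, "param_grid"))
  if (length(counts) == 0) stop("no counts to fit", call. = FALSE)
  if (any(counts < 0) || any(counts > grid$m_max))
    stop("counts outside grid support; renormalize first", call. = FALSE)
  h <- tabulate(counts + 1L, nbins = grid$m_max + 1L)
  ll <- drop(grid$log_pmf %*% h)
  i <- which.max(ll)
  list(params = grid_params(grid, i), log_lik = ll[i], index = i)
}

# Vectorized per-(gene, cluster) grid fits: one histogram column per fit,
# a single matrix product against the log-PMF cache, then column argmax.
# counts: cells x genes; membership: list of row-index vectors, one per
# cluster. Returns genes x clusters matrix of grid row indices.
fit_idx_matrix <- function(counts, membership, grid) {
  g <- ncol(counts)
  k <- length(membership)
  H <- matrix(0, grid$m_max + 1L, g * k)
  col <- 0L
  for (kk in seq_len(k)) {
    rows <- membership[[kk]]
    for (gg in seq_len(g)) {
      col <- col + 1L
      H[, col] <- tabulate(counts[rows, gg] + 1L, nbins = grid$m_max + 1L)
    }
  }
  ll <- grid$log_pmf %*% H
  idx <- max.col(t(ll), ties.method = "first")
  matrix(idx, nrow = g, ncol = k)
}
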