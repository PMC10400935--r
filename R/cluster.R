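#' Log-likelihood of one cell under a set of per-gene parameters
#'
#' The cell likelihood is the joint probability of the cell's counts,
#' i.e. the product over genes of the stationary telegraph probabilities;
#' this returns its logarithm (always <= 0).
#'
#' @param cell_counts Integer vector, one count per gene.
#' @param gene_params Either an integer vector of grid row indices (one
#'   per gene, using the cached PMFs) or a list of [telegraph_params()].
#' @param grid A [param_grid()].
#' @return A single non-positive number.
#' @export
cell_log_likelihood <- function(cell_counts, gene_params, grid) {
  stopifnot(inherits(grid, "param_grid"))
  g <- length(cell_counts)
  if (length(gene_params) != g)
    stop("one parameter set per gene is required", call. = FALSE)
  if (any(cell_counts < 0) || any(cell_counts > grid$m_max))
    stop("counts outside grid support", call. = FALSE)
  if (is.numeric(gene_params)) {
    sum(grid$log_pmf[cbind(as.integer(gene_params), cell_counts + 1L)])
  } else {
    sum(vapply(seq_len(g), function(i)
      -gene_nll(cell_counts[i], gene_params[[i]], grid), numeric(1)))
  }
}

# Internal: per-cell log-likelihood matrix (cells x K) for integer counts.
loglik_matrix <- function(counts, fit_idx, grid) {
  .cell_cluster_loglik(storage_int(counts), grid$log_pmf,
                       storage_int(fit_idx))
}

storage_int <- function(m) {
  if (!is.integer(m)) storage.mode(m) <- "integer"
  m
}

check_support <- function(counts, grid) {
  if (min(counts) < 0 || max(counts) > grid$m_max)
    stop("counts outside grid support 0..", grid$m_max,
         "; run normalize_counts first", call. = FALSE)
  invisible(counts)
}

make_clustering <- function(counts, labels, grid, objective = NULL) {
  k <- max(labels)
  membership <- split(seq_len(nrow(counts)), factor(labels, levels = 1:k))
  if (any(lengths(membership) == 0))
    stop("internal error: empty cluster in final assignment", call. = FALSE)
  fit_idx <- fit_idx_matrix(storage_int(counts), membership, grid)
  ll_mat <- loglik_matrix(counts, fit_idx, grid)
  cell_ll <- ll_mat[cbind(seq_along(labels), labels)]
  structure(list(labels = stats::setNames(labels, rownames(counts)),
                 K = k, fit_idx = fit_idx,
                 cell_log_lik = cell_ll,
                 total_log_likelihood = sum(cell_ll),
                 objective = objective,
                 gene_ids = colnames(counts)),
            class = "telegraph_clustering")
}

#' @export
print.telegraph_clustering <- function(x, ...) {
  cat(sprintf("telegraph clustering: %d cells in %d clusters, total log-likelihood %.2f\n",
              length(x$labels), x$K, x$total_log_likelihood))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Likelihood-greedy cell clustering
#'
#' Coordinate ascent on the total cell log-likelihood: starting from a
#' seeded random partition, alternately (i) refit the per-(gene, cluster)
#' telegraph parameters by grid maximum likelihood and (ii) reassign every
#' cell to the cluster under which its log-likelihood is largest, until
#' the labels are stable or `max_iter` is reached. Clusters emptied by a
#' reassignment are repaired by moving in the globally worst-fitting cell.
#' The recorded objective (total log-likelihood after each refit) is
#' non-decreasing.
#'
#' @param counts Integer cells x genes matrix (within grid support).
#' @param k Number of clusters (`1 <= k <=` number of cells).
#' @param grid A [param_grid()].
#' @param seed Integer seed for the initial partition.
#' @param max_iter Iteration cap.
#' @return A `telegraph_clustering` object: per-cell `labels`, per-(gene,
#'   cluster) grid indices `fit_idx`, per-cell log-likelihoods, the total,
#'   and the `objective` trace.
#' @export
greedy_cluster <- function(counts, k, grid, seed, max_iter = 100) {
  n <- nrow(counts)
  if (k > n) stop("more clusters than cells", call. = FALSE)
  stopifnot(k >= 1)
  counts <- storage_int(counts)
  if (max(counts) > grid$m_max)
    stop("counts exceed grid m_max; run normalize_counts first", call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(seed)
  labels <- sample(rep_len(seq_len(k), n))
  objective <- numeric(0)
  for (iter in seq_len(max_iter)) {
    membership <- split(seq_len(n), factor(labels, levels = 1:k))
    fit_idx <- fit_idx_matrix(counts, membership, grid)
    ll_mat <- loglik_matrix(counts, fit_idx, grid)
    objective <- c(objective, sum(ll_mat[cbind(seq_len(n), labels)]))
    new_labels <- max.col(ll_mat, ties.method = "first")
    # repair: clusters left empty get the globally worst-fitting cell
    repeat {
      sizes <- tabulate(new_labels, nbins = k)
      empty <- which(sizes == 0)
      if (length(empty) == 0) break
      cur_ll <- ll_mat[cbind(seq_len(n), new_labels)]
      cur_ll[sizes[new_labels] == 1] <- Inf  # don't empty a singleton
      worst <- which.min(cur_ll)
      new_labels[worst] <- empty[1]
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  make_clustering(counts, labels, grid, objective = objective)
}

#' Consensus matrix over repeated greedy clusterings
#'
#' Runs [greedy_cluster()] `n_runs` times with distinct seeds derived from
#' the master seed and counts, for every pair of cells, how often the two
#' land in the same cluster.
#'
#' @inheritParams greedy_cluster
#' @param n_runs Number of greedy runs.
#' @param max_iter Per-run iteration cap.
#' @return A `consensus_matrix` object: integer cells x cells co-clustering
#'   `counts` (diagonal = `n_runs`) and `n_runs`.
#' @export
consensus <- function(counts, k, grid, n_runs, seed, max_iter = 100) {
  stopifnot(n_runs >= 1)
  n <- nrow(counts)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max %/% 2, n_runs)
  cm <- matrix(0L, n, n)
  for (r in seq_len(n_runs)) {
    lab <- greedy_cluster(counts, k, grid, seed = run_seeds[r],
                          max_iter = max_iter)$labels
    cm <- cm + outer(lab, lab, "==")
  }
  dimnames(cm) <- list(rownames(counts), rownames(counts))
  structure(list(counts = cm, n_runs = n_runs), class = "consensus_matrix")
}

#' Final cluster assignment by k-medoids on the consensus matrix
#'
#' Partitions cells with k-medoids (PAM) on the dissimilarity
#' `1 - consensus / n_runs`, then refits the per-(gene, cluster) telegraph
#' parameters by grid maximum likelihood.
#'
#' @param cons A `consensus_matrix` from [consensus()].
#' @param k Number of clusters.
#' @param counts The integer cells x genes matrix the consensus was built
#'   from (used to refit parameters).
#' @param grid A [param_grid()].
#' @return A `telegraph_clustering` object.
#' @export
finalize_kmedoids <- function(cons, k, counts, grid) {
  stopifnot(inherits(cons, "consensus_matrix"))
  n <- nrow(cons$counts)
  stopifnot(k <= n)
  d <- 1 - cons$counts / cons$n_runs
  diag(d) <- 0
  off <- d[upper.tri(d)]
  if (k > 1 && length(off) && diff(range(off)) == 0)
    warning("degenerate consensus: all pairs equally similar; split is arbitrary")
  if (k == n) {
    labels <- seq_len(n)
  } else {
    labels <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE,
                           cluster.only = TRUE)
  }
  make_clustering(storage_int(counts), as.integer(labels), grid)
}

#' Eigengap estimate of the number of clusters
#'
#' Computes the symmetric normalized Laplacian of the consensus similarity
#' and returns the `K` in `2..k_max` with the largest gap between
#' consecutive eigenvalues. If the similarity graph is disconnected the
#' number of connected components is returned (when `<= k_max`); if every
#' gap is degenerate the convention is to return 2 with a warning.
#'
#' @param cons A `consensus_matrix`.
#' @param k_max Largest number of clusters considered.
#' @return Integer `K`.
#' @export
eigengap_k <- function(cons, k_max) {
  stopifnot(inherits(cons, "consensus_matrix"), k_max >= 2)
  s <- cons$counts / cons$n_runs
  n <- nrow(s)
  k_max <- min(k_max, n - 1)
  deg <- rowSums(s)
  inv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  lap <- diag(n) - (inv * t(inv * s))   # I - D^-1/2 S D^-1/2
  ev <- sort(eigen(lap, symmetric = TRUE, only.values = TRUE)$values)
  n_comp <- sum(ev < 1e-10)
  if (n_comp > 1 && n_comp <= k_max) return(as.integer(n_comp))
  gaps <- diff(ev)[seq(2, k_max)]      # gap after eigenvalue k, k = 2..k_max
  if (max(gaps) < 1e-10) {
    warning("no informative eigengap; returning K = 2")
    return(2L)
  }
  as.integer(which.max(gaps) + 1L)
}

#' Full consensus clustering of cells
#'
#' Convenience wrapper chaining [consensus()], [eigengap_k()] (when `k` is
#' not given) and [finalize_kmedoids()].
#'
#' @inheritParams consensus
#' @param k Number of clusters, or `NULL` to choose it by the eigengap
#'   heuristic up to `k_max`.
#' @param k_max Upper bound for the eigengap search.
#' @return A `telegraph_clustering` with the consensus matrix attached as
#'   `$consensus`.
#' @export
cluster_cells <- function(counts, grid, k = NULL, k_max = 10, n_runs = 50,
                          seed = 42, max_iter = 100) {
  k_cons <- if (is.null(k)) k_max else k
  cons <- consensus(counts, k_cons, grid, n_runs = n_runs, seed = seed,
                    max_iter = max_iter)
  if (is.null(k)) k <- eigengap_k(cons, k_max)
  res <- finalize_kmedoids(cons, k, counts, grid)
  res$consensus <- cons
  res
}

#' Fitted telegraph parameters per gene and cluster
#'
#' @param clustering A `telegraph_clustering`.
#' @param grid The [param_grid()] used for the fit.
#' @return Data frame with one row per (gene, cluster): the three rates,
#'   burst size `theta_t / theta_off` and burst frequency `theta_on`.
#' @export
cluster_params_table <- function(clustering, grid) {
  g <- nrow(clustering$fit_idx)
  k <- ncol(clustering$fit_idx)
  idx <- as.vector(clustering$fit_idx)
  data.frame(
    gene = rep(clustering$gene_ids %||% seq_len(g), k),
    cluster = rep(seq_len(k), each = g),
    theta_on = grid$points$theta_on[idx],
    theta_off = grid$points$theta_off[idx],
    theta_t = grid$points$theta_t[idx],
    burst_size = grid$points$theta_t[idx] / grid$points$theta_off[idx],
    burst_frequency = grid$points$theta_on[idx],
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
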