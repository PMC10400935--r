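#' Likelihood-based distance between two cell clusters
#'
#' The distance is the average decrease in per-cell log-likelihood when
#' the two clusters are refit as a single cluster: pooled telegraph
#' parameters are refit per gene on the union of cells, and the distance
#' is the mean over those cells of (own-cluster log-likelihood - pooled
#' log-likelihood). Symmetric, and ~0 (up to grid resolution) for clusters
#' generated from identical distributions.
#'
#' @param counts Integer cells x genes matrix.
#' @param labels Integer cluster label per cell.
#' @param k1,k2 The two cluster indices.
#' @param grid A [param_grid()].
#' @return A single number (>= 0 up to grid resolution).
#' @export
cluster_distance <- function(counts, labels, k1, k2, grid) {
  stopifnot(k1 != k2)
  counts <- storage_int(counts)
  check_support(counts, grid)
  i1 <- which(labels == k1); i2 <- which(labels == k2)
  if (!length(i1) || !length(i2)) stop("empty cluster", call. = FALSE)
  u <- c(i1, i2)
  fit <- fit_idx_matrix(counts, list(i1, i2, u), grid)
  ll <- loglik_matrix(counts[u, , drop = FALSE], fit, grid)
  own <- c(ll[seq_along(i1), 1], ll[length(i1) + seq_along(i2), 2])
  mean(own - ll[, 3])
}

# All pairwise cluster distances as a symmetric K x K matrix.
cluster_distance_matrix <- function(counts, labels, grid) {
  k <- max(labels)
  d <- matrix(0, k, k)
  for (a in seq_len(k - 1))
    for (b in (a + 1):k)
      d[a, b] <- d[b, a] <- cluster_distance(counts, labels, a, b, grid)
  d
}

#' Build the lineage progression graph from cluster distances
#'
#' Edges between clusters are added in increasing order of cluster
#' distance (ties by cluster-index order) until every cluster is connected
#' to the rest, or further until `max_edges` edges when requested. Cluster
#' pseudotimes are assigned from graph-hop depth below the root, scaled
#' along each branch so that the root sits at 0 and every leaf at 1.
#'
#' @param distances Symmetric K x K matrix of cluster distances.
#' @param root Root cluster index (earliest cell state).
#' @param max_edges Optional total number of edges (>= the number needed
#'   for connectivity).
#' @return A `lineage_graph`: `edges` (k1, k2, distance), `all_pairs` with
#'   an `in_graph` flag, per-cluster `depth` and `pseudotime`, and `root`.
#' @export
build_lineage <- function(distances, root, max_edges = NULL) {
  k <- nrow(distances)
  stopifnot(ncol(distances) == k, root >= 1, root <= k)
  pairs <- which(upper.tri(distances), arr.ind = TRUE)
  ord <- order(distances[pairs], pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  dvals <- distances[pairs]
  gr <- igraph::make_empty_graph(n = k, directed = FALSE)
  in_graph <- logical(nrow(pairs))
  comp <- seq_len(k)
  for (i in seq_len(nrow(pairs))) {
    a <- comp[pairs[i, 1]]; b <- comp[pairs[i, 2]]
    if (a == b) next  # endpoints already connected through shorter edges
    gr <- igraph::add_edges(gr, pairs[i, ])
    in_graph[i] <- TRUE
    comp[comp == b] <- a
    if (length(unique(comp)) == 1) break
  }
  if (!is.null(max_edges)) {
    for (i in which(!in_graph)) {
      if (igraph::ecount(gr) >= max_edges) break
      gr <- igraph::add_edges(gr, pairs[i, ])
      in_graph[i] <- TRUE
    }
  }
  edges <- data.frame(k1 = pairs[in_graph, 1], k2 = pairs[in_graph, 2],
                      distance = dvals[in_graph])
  depth <- as.integer(igraph::distances(gr, v = root)[1, ])
  # scale each node by the deepest leaf reachable through it so that the
  # root maps to 0 and every terminal fate to 1
  bfs <- igraph::bfs(gr, root = root, father = TRUE)
  father <- as.integer(bfs$father)
  subtree_max <- depth
  for (v in order(depth, decreasing = TRUE)) {
    f <- father[v]
    if (!is.na(f) && subtree_max[v] > subtree_max[f])
      subtree_max[f] <- subtree_max[v]
  }
  pt <- ifelse(subtree_max > 0, depth / subtree_max, 0)
  structure(list(edges = edges,
                 all_pairs = data.frame(k1 = pairs[, 1], k2 = pairs[, 2],
                                        distance = dvals,
                                        in_graph = in_graph),
                 root = as.integer(root), K = k,
                 depth = depth, pseudotime = pt,
                 igraph = gr),
            class = "lineage_graph")
}

#' @export
print.lineage_graph <- function(x, ...) {
  cat(sprintf("lineage graph: %d clusters, root %d\n", x$K, x$root))
  print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Infer the lineage graph for a clustering
#'
#' Computes all pairwise [cluster_distance()]s and calls
#' [build_lineage()]. The root is taken as the cluster with the smallest
#' mean capture time when capture times are available; otherwise `root`
#' must be given.
#'
#' @param counts Integer cells x genes matrix.
#' @param clustering A `telegraph_clustering`.
#' @param grid A [param_grid()].
#' @param root Root cluster index (overrides capture times).
#' @param capture_time Optional per-cell capture times.
#' @param max_edges Passed to [build_lineage()].
#' @return A `lineage_graph`.
#' @export
infer_lineage <- function(counts, clustering, grid, root = NULL,
                          capture_time = NULL, max_edges = NULL) {
  labels <- clustering$labels
  if (is.null(capture_time)) capture_time <- capture_time_of(counts)
  if (is.null(root)) {
    if (is.null(capture_time))
      stop("no capture times available; specify the root cluster",
           call. = FALSE)
    mean_t <- tapply(capture_time, labels, mean)
    root <- as.integer(names(mean_t)[which.min(mean_t)])
  }
  d <- cluster_distance_matrix(counts, labels, grid)
  build_lineage(d, root = root, max_edges = max_edges)
}

#' Place every cell on a lineage edge by likelihood interpolation
#'
#' For each edge adjacent to a cell's cluster and each interpolation
#' fraction `s` in `s_grid`, the per-gene count probability is the mixture
#' `(1 - s) P_k1(m) + s P_k2(m)` of the two endpoint clusters' stationary
#' distributions; the cell's log-likelihood at `(edge, s)` is the sum of
#' log mixture probabilities over genes. Each cell is assigned the
#' maximizing `(edge, s)` (ties: lower edge index, then smaller `s`), its
#' transcriptional uncertainty is `NLL = -max log-likelihood`, and its
#' pseudotime interpolates the endpoint clusters' pseudotimes at `s`.
#'
#' @param counts Integer cells x genes matrix.
#' @param clustering A `telegraph_clustering`.
#' @param graph A `lineage_graph`.
#' @param grid A [param_grid()].
#' @param s_grid Interpolation fractions in `[0, 1]`.
#' @return A `cell_placement`: `placements` data frame (cell_id, cluster,
#'   k1, k2, s, log_lik, nll, pseudotime) and the per-gene NLL matrix
#'   `gene_nll` (cells x genes) evaluated at each cell's optimum.
#' @export
place_cells <- function(counts, clustering, graph, grid,
                        s_grid = seq(0, 1, length.out = 21)) {
  counts <- storage_int(counts)
  check_support(counts, grid)
  n <- nrow(counts); g <- ncol(counts)
  labels <- clustering$labels
  edges <- graph$edges
  best <- data.frame(cell_id = rownames(counts) %||% as.character(seq_len(n)),
                     cluster = as.integer(labels), k1 = NA_integer_,
                     k2 = NA_integer_, s = NA_real_, log_lik = -Inf,
                     nll = NA_real_, pseudotime = NA_real_,
                     stringsAsFactors = FALSE)
  gene_nll_mat <- matrix(NA_real_, n, g,
                         dimnames = list(rownames(counts), colnames(counts)))
  for (cl in sort(unique(labels))) {
    cells <- which(labels == cl)
    adj <- which(edges$k1 == cl | edges$k2 == cl)
    if (!length(adj))
      stop("cluster ", cl, " has no adjacent lineage edge", call. = FALSE)
    for (e in adj) {
      a <- edges$k1[e]; b <- edges$k2[e]
      pa <- prob_matrix(counts, cells, clustering$fit_idx[, a], grid)
      pb <- prob_matrix(counts, cells, clustering$fit_idx[, b], grid)
      if (any(pa == 0 & pb == 0))
        stop("zero mixture probability for an observed count; ",
             "increase m_max", call. = FALSE)
      for (s in s_grid) {
        mix <- (1 - s) * pa + s * pb
        ll <- rowSums(log(mix))
        improve <- ll > best$log_lik[cells]
        if (any(improve)) {
          ii <- cells[improve]
          best$k1[ii] <- a; best$k2[ii] <- b; best$s[ii] <- s
          best$log_lik[ii] <- ll[improve]
          gene_nll_mat[ii, ] <- -log(mix[improve, , drop = FALSE])
        }
      }
    }
  }
  best$nll <- -best$log_lik
  best$pseudotime <- (1 - best$s) * graph$pseudotime[best$k1] +
    best$s * graph$pseudotime[best$k2]
  structure(list(placements = best, gene_nll = gene_nll_mat,
                 s_grid = s_grid),
            class = "cell_placement")
}

# Per-gene stationary probabilities of observed counts for a set of cells
# under one cluster's fitted grid rows: (length(cells)) x G.
prob_matrix <- function(counts, cells, fit_idx_col, grid) {
  sub <- counts[cells, , drop = FALSE]
  idx <- cbind(rep(as.integer(fit_idx_col), each = length(cells)),
               as.vector(sub) + 1L)
  matrix(grid$pmf[idx], nrow = length(cells))
}

#' Pseudotime of placed cells
#'
#' Linear interpolation of the two adjacent clusters' pseudotimes at each
#' cell's fractional position `s` (the value already stored by
#' [place_cells()]); exposed for recomputation against a different graph.
#'
#' @param placement A `cell_placement` or its `placements` data frame.
#' @param graph A `lineage_graph`.
#' @return Numeric vector of pseudotimes in `[0, 1]`.
#' @export
cell_pseudotime <- function(placement, graph) {
  df <- if (inherits(placement, "cell_placement")) placement$placements
        else placement
  (1 - df$s) * graph$pseudotime[df$k1] + df$s * graph$pseudotime[df$k2]
}

#' Root-to-leaf cluster paths of a lineage graph
#'
#' @param graph A `lineage_graph`.
#' @return Named list of integer cluster sequences, one per leaf.
#' @export
lineage_paths <- function(graph) {
  deg <- igraph::degree(graph$igraph)
  leaves <- setdiff(which(deg == 1), graph$root)
  if (!length(leaves)) leaves <- which.max(graph$depth)
  paths <- igraph::shortest_paths(graph$igraph, from = graph$root,
                                  to = leaves)$vpath
  stats::setNames(lapply(paths, as.integer),
                  paste0("leaf_", leaves))
}
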