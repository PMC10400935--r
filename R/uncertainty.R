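#' Mean per-gene uncertainty per cluster
#'
#' Averages the per-gene per-cell NLL over the cells of each cluster:
#' `NLLbar[g, k] = sum_{n in k} NLL[g, n] / N_k`.
#'
#' @param gene_nll Cells x genes matrix of per-gene NLL values (from
#'   [place_cells()]).
#' @param labels Integer cluster label per cell.
#' @return Genes x clusters matrix.
#' @export
mean_gene_cluster_nll <- function(gene_nll, labels) {
  k <- max(labels)
  sizes <- tabulate(labels, nbins = k)
  if (any(sizes == 0)) stop("empty cluster", call. = FALSE)
  out <- matrix(as.numeric(vapply(seq_len(k), function(kk)
    colMeans(gene_nll[labels == kk, , drop = FALSE]),
    numeric(ncol(gene_nll)))), ncol = k)
  dimnames(out) <- list(colnames(gene_nll), seq_len(k))
  out
}

#' Moving-average uncertainty along pseudotime
#'
#' Cells are sorted by pseudotime (ties by cell id) and averaged in a
#' sliding window of `ceil(window_fraction * N)` cells with stride 1; each
#' window reports its mean pseudotime and mean NLL.
#'
#' @param pseudotime,nll Equal-length vectors (one entry per cell).
#' @param cell_id Optional ids used to break pseudotime ties.
#' @param window_fraction Window length as a fraction of the cells.
#' @return Data frame with columns `pseudotime` and `nll`, one row per
#'   window position.
#' @export
moving_average_nll <- function(pseudotime, nll, cell_id = NULL,
                               window_fraction = 0.10) {
  n <- length(pseudotime)
  stopifnot(n >= 1, length(nll) == n)
  if (is.null(cell_id)) cell_id <- seq_len(n)
  ord <- order(pseudotime, cell_id)
  pt <- pseudotime[ord]; y <- nll[ord]
  w <- max(1L, as.integer(ceiling(window_fraction * n)))
  nw <- n - w + 1L
  cpt <- c(0, cumsum(pt)); cy <- c(0, cumsum(y))
  i <- seq_len(nw)
  data.frame(pseudotime = (cpt[i + w] - cpt[i]) / w,
             nll = (cy[i + w] - cy[i]) / w)
}

#' Moving-average uncertainty along each root-to-leaf path
#'
#' Restricts the placed cells to those whose assigned edge lies on a given
#' root-to-leaf cluster path and applies [moving_average_nll()] per path.
#'
#' @param placement A `cell_placement`.
#' @param graph A `lineage_graph`.
#' @param window_fraction Passed to [moving_average_nll()].
#' @return Named list (one per leaf) of moving-average data frames; each
#'   carries the path as an attribute `"path"`.
#' @export
nll_along_paths <- function(placement, graph, window_fraction = 0.10) {
  df <- placement$placements
  lapply(lineage_paths(graph), function(path) {
    on_path <- df$k1 %in% path & df$k2 %in% path
    out <- moving_average_nll(df$pseudotime[on_path], df$nll[on_path],
                              df$cell_id[on_path], window_fraction)
    attr(out, "path") <- path
    out
  })
}

#' High-uncertainty genes per cluster
#'
#' A gene is called high-uncertainty in a cluster when its per-cell NLL
#' exceeds `delta` in at least `frac_cells` of the cluster's cells, where
#' `delta` is `n_sd` standard deviations above the mean of all entries of
#' the gene/cell NLL matrix.
#'
#' @param gene_nll Cells x genes NLL matrix.
#' @param labels Integer cluster label per cell.
#' @param frac_cells Required fraction of cells above threshold.
#' @param n_sd Number of standard deviations defining the threshold.
#' @return List with `delta` and `genes`, a per-cluster list of gene
#'   names.
#' @export
high_uncertainty_genes <- function(gene_nll, labels, frac_cells = 0.30,
                                   n_sd = 3) {
  stopifnot(length(gene_nll) > 0)
  delta <- mean(gene_nll) + n_sd * stats::sd(as.vector(gene_nll))
  k <- max(labels)
  genes <- colnames(gene_nll) %||% as.character(seq_len(ncol(gene_nll)))
  sets <- lapply(seq_len(k), function(kk) {
    sub <- gene_nll[labels == kk, , drop = FALSE]
    hits <- colSums(sub > delta)
    genes[hits >= frac_cells * nrow(sub)]
  })
  list(delta = delta, genes = stats::setNames(sets, seq_len(k)))
}

#' Two-dimensional embedding of expression profiles
#'
#' Genes are z-scored across cells (constant genes are dropped with a
#' warning) and projected onto the first two principal components, with a
#' deterministic sign convention: each component is flipped so that its
#' largest-magnitude gene loading is positive. A custom embedding can be
#' supplied as a function taking the z-scored matrix and returning an
#' N x 2 coordinate matrix (e.g. a seeded t-SNE).
#'
#' @param mat Cells x genes matrix (>= 2 genes after dropping constants).
#' @param method `"pca"` or a function of the z-scored matrix.
#' @return N x 2 numeric matrix of coordinates.
#' @export
embed_2d <- function(mat, method = "pca") {
  v <- apply(mat, 2, stats::sd)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " constant gene(s) before z-scoring")
    mat <- mat[, v > 0, drop = FALSE]
    v <- v[v > 0]
  }
  if (ncol(mat) < 2) stop("need at least 2 non-constant genes", call. = FALSE)
  z <- scale(mat)
  if (is.function(method)) {
    xy <- method(z)
    stopifnot(nrow(xy) == nrow(mat), ncol(xy) == 2)
    return(xy)
  }
  stopifnot(identical(method, "pca"))
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) rot[, j] <- -rot[, j]
  }
  xy <- z %*% rot
  dimnames(xy) <- list(rownames(mat), c("PC1", "PC2"))
  xy
}

#' Fit the uncertainty landscape surface
#'
#' Estimates NLL heights on a regular `grid_n` x `grid_n` grid spanning
#' the 2-D embedding, in the manner of scattered-data surface fitters:
#' each data point constrains the surface through bilinear interpolation
#' from its four surrounding grid nodes, and a second-difference
#' (Laplacian) roughness penalty with weight `smoothness` regularizes the
#' under-constrained nodes. Constants and planes are in the penalty's
#' null space and are reproduced exactly.
#'
#' @param coords N x 2 matrix of embedding coordinates.
#' @param nll Per-cell NLL values.
#' @param grid_n Nodes per axis.
#' @param smoothness Roughness penalty weight (> 0).
#' @return An `uncertainty_landscape`: node axes `x`, `y`, height matrix
#'   `z` (`grid_n` x `grid_n`, rows indexing `x`), plus the inputs.
#' @export
landscape_surface <- function(coords, nll, grid_n = 30, smoothness = 1) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n == length(nll), n >= 3, grid_n >= 3)
  xr <- range(coords[, 1]); yr <- range(coords[, 2])
  if (diff(xr) == 0 || diff(yr) == 0)
    stop("collinear coordinates: landscape needs 2-D spread", call. = FALSE)
  xg <- seq(xr[1], xr[2], length.out = grid_n)
  yg <- seq(yr[1], yr[2], length.out = grid_n)
  dx <- xg[2] - xg[1]; dy <- yg[2] - yg[1]
  node <- function(ix, iy) (iy - 1L) * grid_n + ix
  ix <- pmin(pmax(findInterval(coords[, 1], xg), 1L), grid_n - 1L)
  iy <- pmin(pmax(findInterval(coords[, 2], yg), 1L), grid_n - 1L)
  tx <- (coords[, 1] - xg[ix]) / dx
  ty <- (coords[, 2] - yg[iy]) / dy
  m <- grid_n * grid_n
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n), 4),
    j = c(node(ix, iy), node(ix + 1L, iy), node(ix, iy + 1L),
          node(ix + 1L, iy + 1L)),
    x = c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty),
    dims = c(n, m))
  # second differences along x (within grid columns of constant y) ...
  i2 <- 2:(grid_n - 1)
  rx <- expand.grid(ix = i2, iy = seq_len(grid_n))
  ry <- expand.grid(ix = seq_len(grid_n), iy = i2)
  L <- rbind(
    Matrix::sparseMatrix(
      i = rep(seq_len(nrow(rx)), 3),
      j = c(node(rx$ix - 1L, rx$iy), node(rx$ix, rx$iy),
            node(rx$ix + 1L, rx$iy)),
      x = rep(c(1, -2, 1), each = nrow(rx)), dims = c(nrow(rx), m)),
    Matrix::sparseMatrix(
      i = rep(seq_len(nrow(ry)), 3),
      j = c(node(ry$ix, ry$iy - 1L), node(ry$ix, ry$iy),
            node(ry$ix, ry$iy + 1L)),
      x = rep(c(1, -2, 1), each = nrow(ry)), dims = c(nrow(ry), m)))
  # scale the penalty relative to the data term (gridfit-style) so that
  # smoothness ~ 1 balances fidelity and roughness
  s_eff <- smoothness * max(Matrix::colSums(abs(A))) /
    max(Matrix::colSums(abs(L)))
  lhs <- Matrix::crossprod(A) + s_eff^2 * Matrix::crossprod(L)
  rhs <- Matrix::crossprod(A, nll)
  z <- tryCatch(as.vector(Matrix::solve(lhs, rhs)), error = function(e) NULL)
  tries <- 0
  while (is.null(z) && tries < 5) {
    tries <- tries + 1
    smoothness <- smoothness * 10
    warning("singular landscape system; increasing smoothness to ",
            smoothness)
    s_eff <- s_eff * 10
    lhs <- Matrix::crossprod(A) + s_eff^2 * Matrix::crossprod(L) +
      Matrix::Diagonal(m, 1e-10)
    z <- tryCatch(as.vector(Matrix::solve(lhs, rhs)), error = function(e) NULL)
  }
  if (is.null(z)) stop("landscape system could not be solved", call. = FALSE)
  structure(list(x = xg, y = yg,
                 z = matrix(z, grid_n, grid_n),  # [ix, iy]
                 coords = coords, nll = nll, grid_n = grid_n,
                 smoothness = smoothness),
            class = "uncertainty_landscape")
}

#' Evaluate a fitted landscape at arbitrary coordinates
#'
#' Bilinear interpolation of the node heights; coordinates outside the
#' grid are clamped to its edge cells.
#'
#' @param landscape An `uncertainty_landscape`.
#' @param coords N x 2 coordinate matrix.
#' @return Numeric vector of surface heights.
#' @export
landscape_interpolate <- function(landscape, coords) {
  coords <- as.matrix(coords)
  xg <- landscape$x; yg <- landscape$y; zz <- landscape$z
  gn <- landscape$grid_n
  dx <- xg[2] - xg[1]; dy <- yg[2] - yg[1]
  ix <- pmin(pmax(findInterval(coords[, 1], xg), 1L), gn - 1L)
  iy <- pmin(pmax(findInterval(coords[, 2], yg), 1L), gn - 1L)
  tx <- pmin(pmax((coords[, 1] - xg[ix]) / dx, 0), 1)
  ty <- pmin(pmax((coords[, 2] - yg[iy]) / dy, 0), 1)
  (1 - tx) * (1 - ty) * zz[cbind(ix, iy)] +
    tx * (1 - ty) * zz[cbind(ix + 1L, iy)] +
    (1 - tx) * ty * zz[cbind(ix, iy + 1L)] +
    tx * ty * zz[cbind(ix + 1L, iy + 1L)]
}
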