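test_that("cluster-averaged gene NLL matches the defining mean", {
  m <- rbind(c(1, 5), c(3, 7))           # cluster of 2 cells
  expect_equal(unname(mean_gene_cluster_nll(m, c(1, 1))),
               cbind(c(2, 6)))
  # a single-cell cluster reports its own values
  m2 <- rbind(c(1, 2), c(9, 4), c(5, 6))
  out <- mean_gene_cluster_nll(m2, c(1, 2, 2))
  expect_equal(unname(out[, 1]), c(1, 2))
  # random toy matrix against an explicit double loop
  set.seed(8)
  m3 <- matrix(rexp(18), 6, 3)
  lab <- c(1, 2, 3, 1, 2, 3)
  out3 <- mean_gene_cluster_nll(m3, lab)
  for (k in 1:3) for (g in 1:3)
    expect_equal(unname(out3[g, k]), mean(m3[lab == k, g]))
  expect_error(mean_gene_cluster_nll(m3, c(1, 1, 1, 1, 1, 3)), "empty")
})

test_that("moving-average NLL follows the windowing contract", {
  # constant series stays constant
  out <- moving_average_nll(seq(0, 1, length.out = 50), rep(2, 50))
  expect_true(all(out$nll == 2))
  # window length: ceil(0.1 * 100) = 10, so 91 windows
  out2 <- moving_average_nll(seq(0, 1, length.out = 100), rnorm(100))
  expect_equal(nrow(out2), 91)
  # brute-force windows on a toy series
  set.seed(9)
  pt <- runif(30); y <- rnorm(30)
  out3 <- moving_average_nll(pt, y, window_fraction = 0.2)
  ord <- order(pt, seq_along(pt)); w <- 6
  for (i in seq_len(30 - w + 1)) {
    expect_equal(out3$nll[i], mean(y[ord][i:(i + w - 1)]))
    expect_equal(out3$pseudotime[i], mean(pt[ord][i:(i + w - 1)]))
  }
})

test_that("high-uncertainty gene rule applies the 3-SD / 30% thresholds", {
  # all entries equal: SD 0, strict inequality selects nothing
  m <- matrix(1, 10, 4)
  out <- high_uncertainty_genes(m, rep(1:2, each = 5))
  expect_true(all(lengths(out$genes) == 0))
  # constructed toy: one gene exceeds delta in 40% of a cluster's cells
  set.seed(10)
  base <- matrix(rnorm(100, mean = 1, sd = 0.01), 20, 5,
                 dimnames = list(NULL, paste0("g", 1:5)))
  lab <- rep(1:2, each = 10)
  delta <- mean(base) + 3 * sd(base)
  hot <- base
  hot[1:4, 3] <- delta + 1          # 40% of cluster 1 above threshold
  hot[11:12, 5] <- delta + 1        # only 20% of cluster 2: excluded
  out2 <- high_uncertainty_genes(hot, lab)
  expect_identical(out2$genes[["1"]], "g3")
  expect_identical(out2$genes[["2"]], character(0))
  # frac_cells = 0: any exceedance includes the gene
  out3 <- high_uncertainty_genes(hot, lab, frac_cells = 0)
  expect_true("g5" %in% out3$genes[["2"]])
})

test_that("PCA embedding is deterministic and matches the eigendecomposition", {
  set.seed(11)
  m <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("g", 1:5)))
  xy <- embed_2d(m)
  z <- scale(m)
  expect_equal(unname(colMeans(z)), rep(0, 5))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 5))
  ev <- eigen(cov(z), symmetric = TRUE)
  for (j in 1:2) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(xy[, j]), unname(drop(z %*% v)), tolerance = 1e-8)
  }
  # exactly planar data reconstructs losslessly from two components
  b <- matrix(rnorm(10), 5, 2)
  planar <- matrix(rnorm(60), 30, 2) %*% t(b)
  colnames(planar) <- paste0("g", 1:5)
  xyp <- embed_2d(planar)
  zp <- scale(planar)
  pc <- prcomp(zp, center = FALSE)
  expect_lt(sum(pc$sdev[3:5]^2), 1e-20)
  # constant gene dropped with warning
  expect_warning(embed_2d(cbind(planar, flat = rep(1, 30))), "constant")
})

test_that("landscape surface reproduces constants and planes and smooths noise", {
  set.seed(12)
  xy <- cbind(runif(400), runif(400))
  # constant field
  s0 <- landscape_surface(xy, rep(3, 400), grid_n = 12)
  expect_lt(max(abs(s0$z - 3)), 1e-8)
  # plane: penalty-free, recovered to near machine precision
  zplane <- 2 * xy[, 1] - xy[, 2] + 0.5
  s1 <- landscape_surface(xy, zplane, grid_n = 12, smoothness = 0.01)
  node_truth <- outer(2 * s1$x, -s1$y, "+") + 0.5
  expect_lt(sqrt(mean((s1$z - node_truth)^2)), 1e-6)
  # smooth bump + noise: node error below the noise SD
  bump <- function(x, y) 5 * exp(-((x - 0.5)^2 + (y - 0.5)^2) / 0.05)
  noise_sd <- 0.5
  zz <- bump(xy[, 1], xy[, 2]) + rnorm(400, 0, noise_sd)
  s2 <- landscape_surface(xy, zz, grid_n = 15, smoothness = 1)
  node_truth2 <- outer(s2$x, s2$y, bump)
  expect_lt(sqrt(mean((s2$z - node_truth2)^2)), noise_sd)
  # 30 x 30 default grid shape
  s3 <- landscape_surface(xy, zz)
  expect_equal(dim(s3$z), c(30, 30))
  expect_equal(length(s3$x), 30)
  # interpolation at the data correlates with the raw heights
  fit_at <- landscape_interpolate(s2, xy)
  expect_gt(cor(fit_at, zz), 0.7)
  expect_error(landscape_surface(cbind(1:5, rep(1, 5)), 1:5), "collinear")
})
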