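#' Define a synthetic lineage scenario
#'
#' A scenario fixes everything the generator needs: a tree of cluster
#' transitions rooted at cluster 1, per-cluster cell numbers, the gene
#' count, which clusters are burst-inflated transition states, the
#' inflation factor applied to their burst kinetics, and the lag (in
#' cluster-depth units) by which the velocity proxy leads the inflation.
#'
#' Every gene carries an "active" kinetic state (expressed, bursty) and a
#' "silent" one (promoter rarely ON, weak transcription). Which genes are
#' active evolves along the tree: each transition edge toggles a balanced,
#' non-overlapping marker block (`p_toggle` of the genes, half switched on
#' and half off), so cluster distances add up along lineage paths and the
#' size of the active program — hence the baseline uncertainty — stays
#' constant; active transcription rates additionally drift by a mild
#' multiplicative random walk (`p_change` of the genes per edge). In each
#' transition cluster a subset of genes (`inflation_fraction`) has burst
#' size multiplied by `inflation` (through `theta_t` and `theta_off`) and
#' burst frequency by `sqrt(inflation)` (through `theta_on`): two of the
#' weakest-expressed active genes, which gives the RNA-velocity proxy a
#' mean-expression signature, and otherwise silent genes, whose
#' de-repression adds variability (uncertainty) at little shift in mean
#' expression — emulating exploratory transcription in transition states.
#'
#' @param topology Two-column integer matrix of directed edges
#'   (parent, child) forming a tree rooted at cluster 1.
#' @param cells_per_cluster Cells simulated per cluster.
#' @param n_genes Number of genes.
#' @param transition_clusters Integer vector of burst-inflated clusters.
#' @param inflation Multiplicative burst-size inflation factor (>= 1).
#' @param inflation_fraction Fraction of genes inflated in a transition
#'   cluster.
#' @param velocity_lag Lead of the velocity proxy, in cluster-depth units.
#' @param p_toggle Fraction of genes toggled between active and silent per
#'   edge (balanced: half on, half off).
#' @param p_change Per-edge fraction of genes whose active transcription
#'   rate drifts (by a random 1.4-2.3x factor, up or down).
#' @param seed Master seed for the scenario.
#' @return A `lineage_scenario` object.
#' @export
lineage_scenario <- function(topology, cells_per_cluster = 100,
                             n_genes = 60, transition_clusters = integer(0),
                             inflation = 5, inflation_fraction = 0.2,
                             velocity_lag = 1, p_toggle = 0.15,
                             p_change = 0.25, seed = 42) {
  topology <- matrix(as.integer(topology), ncol = 2)
  k <- max(topology)
  if (nrow(topology) != k - 1)
    stop("topology must be a tree on clusters 1..K (K-1 edges)",
         call. = FALSE)
  if (anyDuplicated(topology[, 2]) || any(topology[, 2] == 1))
    stop("every cluster except the root needs exactly one parent",
         call. = FALSE)
  gr <- igraph::graph_from_edgelist(topology, directed = TRUE)
  if (!igraph::is_connected(gr, mode = "weak"))
    stop("topology must be connected", call. = FALSE)
  stopifnot(inflation >= 1, velocity_lag >= 0, cells_per_cluster >= 1,
            n_genes >= 1, p_change >= 0, p_change <= 1,
            p_toggle >= 0, p_toggle <= 1,
            inflation_fraction > 0, inflation_fraction <= 1)
  structure(list(topology = topology, K = k,
                 cells_per_cluster = as.integer(cells_per_cluster),
                 n_genes = as.integer(n_genes),
                 transition_clusters = as.integer(transition_clusters),
                 inflation = inflation,
                 inflation_fraction = inflation_fraction,
                 velocity_lag = as.integer(velocity_lag),
                 p_toggle = p_toggle, p_change = p_change,
                 seed = as.integer(seed)),
            class = "lineage_scenario")
}

#' @export
print.lineage_scenario <- function(x, ...) {
  cat(sprintf(
    "lineage scenario: %d clusters (%d cells each), %d genes, seed %d\n",
    x$K, x$cells_per_cluster, x$n_genes, x$seed))
  cat("  edges:", paste(apply(x$topology, 1, paste, collapse = "->"),
                        collapse = ", "), "\n")
  if (length(x$transition_clusters))
    cat("  transition clusters:",
        paste(x$transition_clusters, collapse = ", "),
        sprintf("(burst inflation x%g)\n", x$inflation))
  invisible(x)
}

#' Built-in lineage scenarios
#'
#' Four ready-made scenarios covering the trajectory shapes the analysis
#' targets: `linear-4` and `linear-6` (chains), `bifurcation-5` (one
#' branch point) and `two-bifurcation-7` (two branch points). Transition
#' clusters are the branch points, or the mid-chain cluster for linear
#' topologies.
#'
#' @param seed Master seed applied to every preset.
#' @return Named list of `lineage_scenario` objects.
#' @export
preset_scenarios <- function(seed = 42) {
  chain <- function(k) cbind(1:(k - 1), 2:k)
  list(
    "linear-4" = lineage_scenario(
      chain(4), cells_per_cluster = 100, n_genes = 50,
      transition_clusters = 3, seed = seed),
    "linear-6" = lineage_scenario(
      chain(6), cells_per_cluster = 100, n_genes = 60,
      transition_clusters = 4, seed = seed),
    "bifurcation-5" = lineage_scenario(
      rbind(c(1, 2), c(2, 3), c(3, 4), c(3, 5)),
      cells_per_cluster = 100, n_genes = 60,
      transition_clusters = 3, seed = seed),
    "two-bifurcation-7" = lineage_scenario(
      rbind(c(1, 2), c(2, 3), c(2, 4), c(4, 5), c(5, 6), c(5, 7)),
      cells_per_cluster = 100, n_genes = 60,
      transition_clusters = c(2, 5), seed = seed))
}

scenario_depths <- function(scenario) {
  gr <- igraph::graph_from_edgelist(scenario$topology, directed = TRUE)
  as.integer(igraph::distances(gr, v = 1, mode = "out")[1, ])
}

#' Generate lineage-structured single-cell data with ground truth
#'
#' Draws counts for every cell from the stationary telegraph distribution
#' of its cluster's per-gene parameters, and builds a velocity proxy whose
#' magnitude leads the burst inflation: for a cell in a cluster at depth
#' `d`, the per-gene velocity is the absolute difference between the mean
#' expression of the descendant cluster(s) at depth `d + velocity_lag` and
#' the cell's own cluster mean, plus seeded Gaussian noise. Planted
#' pseudotime is cluster depth / max depth plus jitter (SD 0.02). The
#' whole draw is deterministic given the scenario seed.
#'
#' @param scenario A [lineage_scenario()].
#' @return List with `expression` (cells x genes integer matrix carrying a
#'   `capture_time` attribute equal to cluster depth), `velocity` (cells x
#'   genes), and `truth` (labels, planted pseudotime, depths, per-(gene,
#'   cluster) parameter matrices, burst sizes/frequencies, the lag and the
#'   topology).
#' @export
generate_lineage_data <- function(scenario) {
  stopifnot(inherits(scenario, "lineage_scenario"))
  k <- scenario$K; g <- scenario$n_genes
  nc <- scenario$cells_per_cluster
  n <- k * nc
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(scenario$seed)

  # Gene programs: every gene has "active" kinetics (expressed) and a
  # "silent" variant (promoter rarely ON, weak transcription). Which
  # genes are active evolves along the tree by toggling, and active
  # transcription rates drift by a multiplicative random walk, so
  # adjacent clusters share most of their expression program while
  # distant clusters diverge.
  on_act <- 10^stats::runif(g, -0.3, 0.5)
  off_act <- 10^stats::runif(g, -0.5, 0.5)
  sil_on_ratio <- 10^stats::runif(g, 1.0, 1.2)
  sil_t_ratio <- 10^stats::runif(g, 0.6, 0.8)
  theta_t_act <- matrix(0, g, k)
  theta_t_act[, 1] <- 10^stats::runif(g, 1.0, 1.5)
  active <- matrix(FALSE, g, k)
  active[, 1] <- stats::runif(g) < 0.5
  depths <- scenario_depths(scenario)
  # each edge changes a fixed-size gene budget so that per-edge
  # distances are comparable and the cluster-distance ordering reflects
  # tree adjacency rather than sampling noise in the number of markers
  n_half <- if (scenario$p_toggle == 0) 0L else
    max(1L, round(scenario$p_toggle * g / 2))
  n_chg <- round(scenario$p_change * g)
  avail <- seq_len(g)
  for (e in order(depths[scenario$topology[, 2]])) {
    parent <- scenario$topology[e, 1]; child <- scenario$topology[e, 2]
    theta_t_act[, child] <- theta_t_act[, parent]
    active[, child] <- active[, parent]
    # Balanced toggling (equal numbers switched on and off) keeps the
    # size of each cluster's active program constant, so baseline
    # uncertainty is flat along the lineage and the burst-inflation peak
    # is the dominant NLL feature. Marker blocks are drawn without reuse
    # across edges, so cluster distances add up along lineage paths
    # instead of partially cancelling.
    pool_on <- intersect(avail, which(active[, child]))
    pool_off <- intersect(avail, which(!active[, child]))
    if (length(pool_on) < n_half || length(pool_off) < n_half) {
      avail <- seq_len(g)  # gene pool exhausted on a large tree: recycle
      pool_on <- which(active[, child]); pool_off <- which(!active[, child])
    }
    tog <- c(sample(pool_on, min(n_half, length(pool_on))),
             sample(pool_off, min(n_half, length(pool_off))))
    avail <- setdiff(avail, tog)
    active[tog, child] <- !active[tog, child]
    chg <- sample.int(g, n_chg)
    f <- 2^stats::runif(n_chg, 0.5, 1.2)
    up <- stats::runif(n_chg) < 0.5
    mult <- ifelse(up, f, 1 / f)
    theta_t_act[chg, child] <- pmin(pmax(theta_t_act[chg, child] * mult, 6),
                                    45)
  }
  theta_on <- ifelse(active, on_act, on_act / sil_on_ratio)
  theta_off <- matrix(off_act, g, k)
  theta_t <- ifelse(active, theta_t_act, theta_t_act / sil_t_ratio)
  # Burst inflation in transition states: a seeded subset of the active
  # genes gets burst size x inflation (theta_t and theta_off moving
  # sqrt(inflation) each) and burst frequency x sqrt(inflation)
  # (theta_on). Restricting inflation to a gene subset keeps the
  # transition cluster intermediate between its neighbours, as transition
  # states are in expression space, while still planting a strong
  # burst-kinetics signature.
  sqf <- sqrt(scenario$inflation)
  base_burst_size <- theta_t / theta_off  # pre-inflation burst sizes
  inflated <- matrix(FALSE, g, k)
  for (tc in scenario$transition_clusters) {
    act <- which(active[, tc]); sil <- which(!active[, tc])
    n_inf <- max(1L, round(scenario$inflation_fraction * g))
    n_act <- min(2L, n_inf)
    # inflate the weakest-expressed active genes plus a draw of silent
    # genes: the uncertainty gain depends on the variance ratio while the
    # distortion of cluster distances scales with absolute expression, so
    # this plants a strong burst signature (and a mean-expression change
    # the velocity proxy can see) while keeping the transition state
    # between its lineage neighbours
    pick_act <- act[order(theta_t[act, tc])][seq_len(min(n_act, length(act)))]
    pick_sil <- if (n_inf - length(pick_act) > 0)
      sample(sil, min(n_inf - length(pick_act), length(sil))) else integer(0)
    pick <- c(pick_act, pick_sil)
    inflated[pick, tc] <- TRUE
    theta_t[pick, tc] <- theta_t[pick, tc] * sqf
    theta_off[pick, tc] <- theta_off[pick, tc] / sqf
    theta_on[pick, tc] <- theta_on[pick, tc] * sqf
  }

  labels <- rep(seq_len(k), each = nc)
  counts <- matrix(0L, n, g)
  for (kk in seq_len(k)) {
    rows <- which(labels == kk)
    for (gg in seq_len(g)) {
      p <- stats::rbeta(nc, theta_on[gg, kk], theta_off[gg, kk])
      counts[rows, gg] <- as.integer(stats::rpois(nc, theta_t[gg, kk] * p))
    }
  }
  cell_ids <- sprintf("cell_%04d", seq_len(n))
  gene_ids <- sprintf("g%03d", seq_len(g))
  expr <- expression_matrix(counts, cell_ids, gene_ids,
                            capture_time = depths[labels])

  # planted pseudotime: depth scaled to [0, 1] plus small jitter
  max_depth <- max(depths)
  pt <- depths[labels] / max_depth + stats::rnorm(n, 0, 0.02)
  pt <- pmin(pmax(pt, 0), 1)

  # velocity proxy: forward difference of cluster mean expression at
  # depth d + lag, so its magnitude leads the inflation-driven NLL rise
  mean_expr <- theta_t * theta_on / (theta_on + theta_off)  # g x k
  gr <- igraph::graph_from_edgelist(scenario$topology, directed = TRUE)
  vel_cluster <- matrix(0, g, k)
  for (kk in seq_len(k)) {
    desc <- which(is.finite(igraph::distances(gr, v = kk,
                                              mode = "out")[1, ]))
    ahead <- desc[depths[desc] == depths[kk] + scenario$velocity_lag]
    if (length(ahead)) {
      future <- rowMeans(mean_expr[, ahead, drop = FALSE])
      vel_cluster[, kk] <- abs(future - mean_expr[, kk])
    }
  }
  noise_sd <- 0.05 * max(vel_cluster)
  velocity <- t(vel_cluster[, labels, drop = FALSE]) +
    matrix(stats::rnorm(n * g, 0, noise_sd), n, g)
  dimnames(velocity) <- list(cell_ids, gene_ids)

  list(expression = expr, velocity = velocity,
       truth = list(labels = stats::setNames(labels, cell_ids),
                    pseudotime = stats::setNames(pt, cell_ids),
                    cluster_depth = depths,
                    theta_on = theta_on, theta_off = theta_off,
                    theta_t = theta_t, active = active,
                    inflated = inflated,
                    base_burst_size = base_burst_size,
                    burst_size = theta_t / theta_off,
                    burst_frequency = theta_on,
                    velocity_lag = scenario$velocity_lag,
                    topology = scenario$topology))
}
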