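#' Run the full transcriptional-uncertainty pipeline
#'
#' Orchestrates preprocessing, likelihood-based consensus clustering,
#' lineage inference, cell placement with per-cell/per-gene uncertainty,
#' landscape reconstruction and the burst/velocity statistics, writing
#' every result as a headered CSV plus a manifest recording the
#' configuration, seed and output checksums. Re-running with an identical
#' configuration and inputs reproduces identical files.
#'
#' @param expression Cells x genes matrix (see [expression_matrix()]) or a
#'   path readable by [read_expression()].
#' @param out_dir Output directory (created; partial outputs are removed
#'   on failure).
#' @param config Named list of overrides on [default_config()], or a path
#'   to a flat `key = value` file.
#' @param velocity Optional cells x genes RNA-velocity matrix (or path);
#'   enables the velocity-vs-uncertainty comparison.
#' @param labels Optional precomputed integer cluster labels (skips
#'   clustering; e.g. imported from an external method).
#' @param capture_time Optional per-cell capture times (else taken from
#'   the expression matrix attribute) used to pick the root cluster.
#' @return (Invisibly) a list with every intermediate result.
#' @export
run_pipeline <- function(expression, out_dir, config = list(),
                         velocity = NULL, labels = NULL,
                         capture_time = NULL) {
  cfg <- if (is.character(config)) read_config(config)
         else read_config(NULL, overrides = config)
  if (is.character(expression)) expression <- read_expression(expression)
  if (is.character(velocity)) velocity <- read_expression(velocity)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
    written <<- c(written, path)
    path
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written))

  if (is.null(capture_time)) capture_time <- capture_time_of(expression)

  # --- preprocess -----------------------------------------------------
  mat <- expression
  log_lines <- sprintf("input: %d cells x %d genes", nrow(mat), ncol(mat))
  if (!is.na(cfg$preprocess.min_fraction_expressed))
    mat <- filter_cells(mat, cfg$preprocess.min_fraction_expressed)
  if (!is.na(cfg$preprocess.min_cell_fraction_nonzero))
    mat <- filter_genes(mat, cfg$preprocess.min_cell_fraction_nonzero)
  if (!is.na(cfg$preprocess.n_variable_genes))
    mat <- select_variable_genes(mat,
                                 min(cfg$preprocess.n_variable_genes,
                                     ncol(mat)))
  mat <- normalize_counts(mat, cfg$grid.m_max)
  if (!is.null(capture_time) && is.null(capture_time_of(mat)))
    attr(mat, "capture_time") <- capture_time[rownames(expression) %in%
                                                rownames(mat)]
  log_lines <- c(log_lines,
                 sprintf("after filters: %d cells x %d genes",
                         nrow(mat), ncol(mat)))
  write_expression(mat, file.path(out_dir, "expression_processed.csv"))
  written <- c(written, file.path(out_dir, "expression_processed.csv"))

  grid <- grid_from_config(cfg)

  # --- clustering -----------------------------------------------------
  if (is.null(labels)) {
    clus <- cluster_cells(
      mat, grid,
      k = if (is.na(cfg$cluster.k)) NULL else cfg$cluster.k,
      k_max = cfg$cluster.k_max, n_runs = cfg$cluster.n_runs,
      seed = cfg$seed, max_iter = cfg$cluster.max_iter)
    cm <- clus$consensus$counts
    emit(data.frame(cell_id = rownames(mat), cm, check.names = FALSE),
         "consensus_matrix.csv")
  } else {
    clus <- make_clustering(storage_int(mat), as.integer(labels), grid)
  }
  log_lines <- c(log_lines, sprintf("K = %d clusters", clus$K))
  emit(data.frame(cell_id = names(clus$labels), cluster = clus$labels),
       "cluster_labels.csv")
  ptab <- cluster_params_table(clus, grid)
  emit(ptab, "cluster_params.csv")

  # --- lineage --------------------------------------------------------
  graph <- infer_lineage(
    mat, clus, grid,
    root = if (is.na(cfg$lineage.root)) NULL else cfg$lineage.root,
    capture_time = capture_time_of(mat),
    max_edges = if (is.na(cfg$lineage.max_edges)) NULL
                else cfg$lineage.max_edges)
  emit(graph$all_pairs, "lineage_edges.csv")
  log_lines <- c(log_lines,
                 sprintf("lineage root %d; edges: %s", graph$root,
                         paste(graph$edges$k1, graph$edges$k2, sep = "-",
                               collapse = ", ")))

  # --- uncertainty ----------------------------------------------------
  placement <- place_cells(mat, clus, graph, grid,
                           s_grid = seq(0, 1,
                                        length.out = cfg$lineage.s_grid_n))
  emit(placement$placements, "cell_placements.csv")
  emit(data.frame(cell_id = rownames(placement$gene_nll),
                  placement$gene_nll, check.names = FALSE),
       "gene_cell_nll.csv")

  ma <- nll_along_paths(placement, graph,
                        window_fraction = cfg$uncertainty.window_fraction)
  ma_df <- do.call(rbind, lapply(names(ma), function(nm)
    data.frame(path = nm, ma[[nm]])))
  emit(ma_df, "moving_average_nll.csv")

  hug <- high_uncertainty_genes(placement$gene_nll, clus$labels,
                                frac_cells = cfg$uncertainty.frac_cells,
                                n_sd = cfg$uncertainty.n_sd)
  hug_df <- do.call(rbind, c(list(
    data.frame(cluster = integer(0), gene = character(0))),
    lapply(names(hug$genes), function(kk)
      if (length(hug$genes[[kk]]))
        data.frame(cluster = as.integer(kk), gene = hug$genes[[kk]]))))
  emit(hug_df, "high_uncertainty_genes.csv")

  coords <- embed_2d(mat)
  emit(data.frame(cell_id = rownames(mat), x = coords[, 1],
                  y = coords[, 2]), "embedding.csv")
  surf <- landscape_surface(coords, placement$placements$nll,
                            grid_n = cfg$uncertainty.grid_n,
                            smoothness = cfg$uncertainty.smoothness)
  nodes <- expand.grid(ix = seq_len(surf$grid_n), iy = seq_len(surf$grid_n))
  emit(data.frame(x = surf$x[nodes$ix], y = surf$y[nodes$iy],
                  z = as.vector(surf$z)), "landscape_grid.csv")

  # --- statistics -----------------------------------------------------
  nll_bar <- mean_gene_cluster_nll(placement$gene_nll, clus$labels)
  cors <- burst_uncertainty_table(ptab, nll_bar)
  emit(cors, "correlations.csv")
  velo_summary <- NULL
  lag <- NULL
  if (!is.null(velocity)) {
    velocity <- velocity[rownames(mat), , drop = FALSE]
    velo_summary <- cellwise_velocity_and_nll(velocity, placement$gene_nll)
    velo_summary$pseudotime <- placement$placements$pseudotime
    emit(velo_summary, "velocity_summary.csv")
    va <- binned_series(velo_summary$pseudotime, velo_summary$velocity_norm,
                        cfg$stats.n_bins)
    vb <- binned_series(velo_summary$pseudotime, velo_summary$mean_nll,
                        cfg$stats.n_bins)
    lag <- lagged_cross_correlation(va$value, vb$value, cfg$stats.max_lag)
  }

  # --- manifest -------------------------------------------------------
  manifest <- file.path(out_dir, "manifest.txt")
  cfg_lines <- sprintf("%s = %s", names(cfg),
                       vapply(cfg, function(v) format(v, digits = 15),
                              character(1)))
  sums <- tools::md5sum(sort(written))
  writeLines(c("# burstscape run manifest",
               paste0("package_version = ",
                      as.character(utils::packageVersion("burstscape"))),
               cfg_lines, log_lines,
               sprintf("md5 %s %s", basename(names(sums)), unname(sums))),
             manifest)
  ok <- TRUE
  invisible(list(config = cfg, expression = mat, grid = grid,
                 clustering = clus, graph = graph, placement = placement,
                 moving_average = ma, high_uncertainty = hug,
                 embedding = coords, landscape = surf,
                 nll_bar = nll_bar, correlations = cors,
                 velocity_summary = velo_summary, velocity_lag = lag,
                 files = c(written, manifest)))
}
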