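#' Read an expression (or velocity) matrix
#'
#' Two formats are supported: (a) a delimited table whose first row holds
#' gene ids and whose first column holds cell ids; (b) a MatrixMarket
#' coordinate file accompanied by one-id-per-line cell and gene files.
#' For MatrixMarket input the orientation is resolved against the id
#' files: rows are taken as cells when the row count matches the number of
#' cell ids, otherwise the matrix is transposed.
#'
#' @param path Delimited table, or MatrixMarket `.mtx` file.
#' @param sep Field separator for the delimited format.
#' @param cells_file,genes_file Id files (MatrixMarket format only).
#' @return Cells x genes numeric matrix with dimnames.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, sep = ",", cells_file = NULL,
                            genes_file = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (!is.null(cells_file) || !is.null(genes_file)) {
    if (is.null(cells_file) || is.null(genes_file))
      stop("MatrixMarket input needs both cells_file and genes_file",
           call. = FALSE)
    m <- as.matrix(Matrix::readMM(path))
    cells <- readLines(cells_file)
    genes <- readLines(genes_file)
    if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      # rows already cells
    } else if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      m <- t(m)
    } else {
      stop("MatrixMarket dimensions match neither id file", call. = FALSE)
    }
    return(expression_matrix(m, cell_ids = cells, gene_ids = genes))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  expression_matrix(as.matrix(df))
}

#' Write an expression matrix as a delimited table
#'
#' Mirrors the delimited reader: first row gene ids, first column cell
#' ids. Round-trips integer matrices exactly.
#'
#' @param mat Cells x genes matrix with dimnames.
#' @param path Output file.
#' @param sep Field separator.
#' @export
write_expression <- function(mat, path, sep = ",") {
  df <- data.frame(cell_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Flat named list of every tunable parameter, grouped by dotted prefixes:
#' `grid.*` (fitting grid axes and count cap), `preprocess.*` (filters and
#' variable-gene count; `NA` disables a step), `cluster.*` (number of
#' clusters or eigengap auto-selection, consensus runs), `lineage.*`
#' (likelihood-interpolation resolution, root cluster), `uncertainty.*`
#' (moving-average window, high-uncertainty gene rule, landscape grid and
#' smoothness), `stats.*` (pseudotime bins and maximum lag), and the
#' master `seed`.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 42,
    grid.theta_on_min = 1e-2, grid.theta_on_max = 1e2, grid.theta_on_n = 20,
    grid.theta_off_min = 1e-2, grid.theta_off_max = 1e2, grid.theta_off_n = 20,
    grid.theta_t_min = 0.1, grid.theta_t_max = NA, grid.theta_t_n = 25,
    grid.m_max = 200, grid.n_nodes = 512,
    preprocess.min_fraction_expressed = NA,
    preprocess.min_cell_fraction_nonzero = NA,
    preprocess.n_variable_genes = NA,
    cluster.k = NA, cluster.k_max = 10,
    cluster.n_runs = 50, cluster.max_iter = 100,
    lineage.s_grid_n = 21, lineage.root = NA, lineage.max_edges = NA,
    uncertainty.window_fraction = 0.10,
    uncertainty.frac_cells = 0.30, uncertainty.n_sd = 3,
    uncertainty.grid_n = 30, uncertainty.smoothness = 1,
    stats.n_bins = 20, stats.max_lag = 5
  )
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Keys not present in [default_config()] are rejected before any
#' computation. Values parse as numbers where possible (with `NA` meaning
#' "unset").
#'
#' @param path Configuration file, or `NULL` for pure defaults.
#' @param overrides Named list merged on top (e.g. programmatic settings).
#' @return Full configuration list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  parsed <- list()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2)
        stop("malformed config line: ", ln, call. = FALSE)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      num <- suppressWarnings(as.numeric(val))
      parsed[[key]] <- if (!is.na(num) || identical(toupper(val), "NA"))
        num else val
    }
  }
  parsed[names(overrides)] <- overrides
  unknown <- setdiff(names(parsed), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(parsed)] <- parsed
  cfg
}

# Build the fitting grid described by a configuration list.
grid_from_config <- function(config) {
  tmax <- config$grid.theta_t_max
  if (is.na(tmax)) tmax <- 2 * config$grid.m_max
  param_grid(
    theta_on = lseq(config$grid.theta_on_min, config$grid.theta_on_max,
                    config$grid.theta_on_n),
    theta_off = lseq(config$grid.theta_off_min, config$grid.theta_off_max,
                     config$grid.theta_off_n),
    theta_t = lseq(config$grid.theta_t_min, tmax, config$grid.theta_t_n),
    m_max = config$grid.m_max,
    n_nodes = config$grid.n_nodes)
}
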