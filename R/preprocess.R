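#' Assemble a cells x genes expression matrix
#'
#' The pipeline's working container is a plain numeric matrix with cells in
#' rows (rownames = cell ids) and genes in columns (colnames = gene ids),
#' optionally carrying a per-cell `capture_time` attribute. This helper
#' validates and attaches the pieces.
#'
#' @param values Non-negative numeric matrix, cells x genes.
#' @param cell_ids,gene_ids Unique identifiers; default to existing
#'   dimnames or generated ids.
#' @param capture_time Optional numeric vector, one value per cell.
#' @return The validated matrix with dimnames (and `capture_time`
#'   attribute when supplied).
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values),
                              capture_time = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative", call. = FALSE)
  if (is.null(cell_ids))
    cell_ids <- sprintf("cell_%04d", seq_len(nrow(values)))
  if (is.null(gene_ids))
    gene_ids <- sprintf("gene_%04d", seq_len(ncol(values)))
  if (anyDuplicated(cell_ids) || anyDuplicated(gene_ids))
    stop("cell and gene ids must be unique", call. = FALSE)
  dimnames(values) <- list(as.character(cell_ids), as.character(gene_ids))
  if (!is.null(capture_time)) {
    stopifnot(length(capture_time) == nrow(values))
    attr(values, "capture_time") <- as.numeric(capture_time)
  }
  values
}

capture_time_of <- function(mat) attr(mat, "capture_time")

# Subset that keeps dimnames and slices the capture_time attribute.
subset_cells <- function(mat, keep) {
  ct <- capture_time_of(mat)
  out <- mat[keep, , drop = FALSE]
  if (!is.null(ct)) attr(out, "capture_time") <- ct[keep]
  out
}

subset_genes <- function(mat, keep) {
  ct <- capture_time_of(mat)
  out <- mat[, keep, drop = FALSE]
  if (!is.null(ct)) attr(out, "capture_time") <- ct
  out
}

#' Normalize expression values onto the model's count support
#'
#' If the matrix-wide maximum exceeds `m_max`, every entry is scaled by the
#' single factor `m_max / max` (preserving relative expression across genes
#' and cells); all entries are then rounded half-up to integers. Zeros are
#' unaffected.
#'
#' @param mat Cells x genes non-negative matrix.
#' @param m_max Largest count supported by the fitting grid.
#' @return Integer-valued matrix with the same dimnames and attributes.
#' @export
normalize_counts <- function(mat, m_max) {
  if (any(mat < 0)) stop("negative expression values", call. = FALSE)
  mx <- max(mat)
  out <- mat
  if (mx > m_max) out <- out * (m_max / mx)
  out[] <- floor(out + 0.5)  # half-up, platform-independent
  ct <- capture_time_of(mat)
  if (!is.null(ct)) attr(out, "capture_time") <- ct
  out
}

#' Filter cells by fraction of expressed genes
#'
#' Keeps cells in which at least `min_fraction_expressed` of the genes have
#' a value greater than zero (e.g. 0.75 reproduces a "remove cells
#' expressing fewer than 75% of genes" rule).
#'
#' @param mat Cells x genes matrix.
#' @param min_fraction_expressed Threshold in `[0, 1]`.
#' @return The matrix restricted to surviving cells.
#' @export
filter_cells <- function(mat, min_fraction_expressed) {
  stopifnot(min_fraction_expressed >= 0, min_fraction_expressed <= 1)
  frac <- rowMeans(mat > 0)
  subset_cells(mat, frac >= min_fraction_expressed)
}

#' Filter genes by fraction of cells with non-zero expression
#'
#' Keeps genes with non-zero values in at least `min_cell_fraction_nonzero`
#' of the cells. A strictly positive but tiny threshold (e.g. `1e-9`)
#' drops all-zero genes only.
#'
#' @param mat Cells x genes matrix.
#' @param min_cell_fraction_nonzero Threshold in `[0, 1]`.
#' @return The matrix restricted to surviving genes.
#' @export
filter_genes <- function(mat, min_cell_fraction_nonzero) {
  stopifnot(min_cell_fraction_nonzero >= 0, min_cell_fraction_nonzero <= 1)
  frac <- colMeans(mat > 0)
  subset_genes(mat, frac >= min_cell_fraction_nonzero)
}

#' Keep the most variable genes
#'
#' Ranks genes by the variance of their (normalized) values across cells
#' and keeps the top `n_genes`; ties are broken by gene-id order. The
#' original column order of the surviving genes is preserved.
#'
#' @param mat Cells x genes matrix.
#' @param n_genes Number of genes to keep (`1 <= n_genes <= G`).
#' @return The matrix restricted to the selected genes.
#' @export
select_variable_genes <- function(mat, n_genes) {
  g <- ncol(mat)
  if (n_genes < 1 || n_genes > g)
    stop("n_genes must be between 1 and the number of genes", call. = FALSE)
  v <- apply(mat, 2, stats::var)
  ord <- order(-v, colnames(mat))
  keep <- sort(ord[seq_len(n_genes)])
  subset_genes(mat, keep)
}
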