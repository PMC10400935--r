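#' Pearson correlation with t score and p-value
#'
#' Standard Pearson correlation together with the significance score
#' `t = r * sqrt((n - 2) / (1 - r^2))`, referred to a t distribution with
#' `n - 2` degrees of freedom (two-sided). A perfect correlation reports
#' `t = Inf` (or `-Inf`) and `p = 0`.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, neither constant.
#' @param pair Optional label for the variable pair.
#' @return A `correlation_record` list: `pair`, `r`, `n`, `t`, `p`.
#' @export
pearson_with_t <- function(x, y, pair = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  r <- stats::cor(x, y)
  t <- if (1 - r^2 < 1e-12) sign(r) * Inf
       else r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  structure(list(pair = pair, r = r, n = n, t = t, p = p),
            class = "correlation_record")
}

#' @export
print.correlation_record <- function(x, ...) {
  cat(sprintf("%s: r = %.4f (n = %d, t = %.3f, p = %.3g)\n",
              x$pair %||% "correlation", x$r, x$n, x$t, x$p))
  invisible(x)
}

#' Correlation of cluster-averaged uncertainty with burst kinetics
#'
#' Flattens burst size `S[g, k] = theta_t / theta_off`, burst frequency
#' `F[g, k] = theta_on` and the cluster-averaged gene NLL over all (gene,
#' cluster) pairs and reports the two Pearson correlations with their t
#' scores, flagging significance at `p <= 0.01`.
#'
#' @param params_table Data frame from [cluster_params_table()].
#' @param nll_bar Genes x clusters matrix from [mean_gene_cluster_nll()]
#'   (same gene order and cluster indexing as the params table).
#' @return Data frame with rows `burst_frequency` and `burst_size`:
#'   columns `variable`, `r`, `n`, `t`, `p`, `significant`.
#' @export
burst_uncertainty_table <- function(params_table, nll_bar) {
  g <- nrow(nll_bar); k <- ncol(nll_bar)
  if (nrow(params_table) != g * k)
    stop("params table and NLL matrix disagree on (gene, cluster) pairs",
         call. = FALSE)
  if (g * k < 3) stop("need at least 3 (gene, cluster) pairs", call. = FALSE)
  nll_flat <- as.vector(nll_bar)  # gene-fastest, matching the table rows
  recs <- list(
    pearson_with_t(params_table$burst_frequency, nll_flat,
                   pair = "burst_frequency"),
    pearson_with_t(params_table$burst_size, nll_flat, pair = "burst_size"))
  do.call(rbind, lapply(recs, function(r)
    data.frame(variable = r$pair, r = r$r, n = r$n, t = r$t, p = r$p,
               significant = r$p <= 0.01, stringsAsFactors = FALSE)))
}

#' Cell-wise RNA-velocity magnitude and mean uncertainty
#'
#' Summarizes each cell by the Euclidean norm of its RNA-velocity vector
#' and by the mean per-gene NLL over the gene panel.
#'
#' @param velocity Cells x genes velocity matrix.
#' @param gene_nll Cells x genes NLL matrix (same cells; the gene panels
#'   may differ in size).
#' @return Data frame: `cell_id`, `velocity_norm`, `mean_nll`.
#' @export
cellwise_velocity_and_nll <- function(velocity, gene_nll) {
  if (nrow(velocity) != nrow(gene_nll))
    stop("velocity and NLL matrices must share cells", call. = FALSE)
  if (ncol(gene_nll) < 1) stop("empty gene panel", call. = FALSE)
  data.frame(
    cell_id = rownames(velocity) %||% as.character(seq_len(nrow(velocity))),
    velocity_norm = sqrt(rowSums(velocity^2)),
    mean_nll = rowMeans(gene_nll),
    stringsAsFactors = FALSE)
}

#' Average a per-cell quantity in equal-count pseudotime bins
#'
#' @param pseudotime,x Equal-length vectors.
#' @param n_bins Number of bins; cells are sorted by pseudotime and split
#'   into `n_bins` nearly equal-count groups.
#' @return Data frame `pseudotime` (bin means) and `value`.
#' @export
binned_series <- function(pseudotime, x, n_bins = 20) {
  n <- length(pseudotime)
  stopifnot(length(x) == n, n_bins >= 2, n >= n_bins)
  ord <- order(pseudotime)
  bin <- ceiling(seq_along(ord) * n_bins / n)
  data.frame(
    pseudotime = as.vector(tapply(pseudotime[ord], bin, mean)),
    value = as.vector(tapply(x[ord], bin, mean)))
}

#' Lagged cross-correlation of two binned series
#'
#' Computes the Pearson correlation of `a` against `b` shifted by each lag
#' in `-max_lag..max_lag` over the truncated overlap, and reports the lag
#' maximizing the correlation (ties: smallest absolute lag). A positive
#' best lag means `a` leads `b`, i.e. `b` reproduces `a` with a delay.
#'
#' @param a,b Equal-length numeric series (e.g. bin means along
#'   pseudotime).
#' @param max_lag Largest lag magnitude tried; overlaps shorter than 3
#'   points are skipped.
#' @return List with `best_lag`, `best_r`, and the full `profile` data
#'   frame (`lag`, `r`).
#' @export
lagged_cross_correlation <- function(a, b, max_lag) {
  n <- length(a)
  stopifnot(length(b) == n, n > max_lag)
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(l) {
    if (l >= 0) { ai <- seq_len(n - l); bi <- ai + l }
    else { bi <- seq_len(n + l); ai <- bi - l }
    if (length(ai) < 3) return(NA_real_)
    if (stats::sd(a[ai]) == 0 || stats::sd(b[bi]) == 0) return(NA_real_)
    stats::cor(a[ai], b[bi])
  }, numeric(1))
  ok <- which(!is.na(r))
  if (!length(ok)) stop("no lag with a valid overlap", call. = FALSE)
  best <- ok[order(-r[ok], abs(lags[ok]), lags[ok])][1]
  list(best_lag = lags[best], best_r = r[best],
       profile = data.frame(lag = lags, r = r))
}
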