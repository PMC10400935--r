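#include <Rcpp.h>
using namespace Rcpp;

// Poisson mixture PMF over counts 0..m_max given quadrature nodes.
// lambda[i] = theta_t * p_i, w[i] normalized Beta quadrature weights
// (sum to 1).  dpois is evaluated by the stable upward recurrence
// P(m+1) = P(m) * lambda / (m + 1) starting from exp(-lambda); all
// lambdas of interest stay below ~745 so exp(-lambda) does not
// underflow before mass reappears near m ~ lambda.
// [[Rcpp::export(name = ".pb_pmf_quad")]]
NumericVector pb_pmf_quad(NumericVector lambda, NumericVector w, int m_max) {
  const int n = lambda.size();
  NumericVector out(m_max + 1);
  std::vector<double> cur(n);
  for (int i = 0; i < n; ++i) cur[i] = std::exp(-lambda[i]);
  for (int m = 0; m <= m_max; ++m) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += w[i] * cur[i];
    out[m] = acc;
    if (m < m_max)
      for (int i = 0; i < n; ++i) cur[i] *= lambda[i] / (m + 1.0);
  }
  return out;
}

// Batch version used when building a parameter grid: one row of
// `lambda_mat` per grid point (nodes already scaled by theta_t), all
// sharing the weight vector `w`.  Returns (n_points) x (m_max+1).
// [[Rcpp::export(name = ".pb_pmf_quad_batch")]]
NumericMatrix pb_pmf_quad_batch(NumericMatrix lambda_mat, NumericVector w,
                                int m_max) {
  const int np = lambda_mat.nrow(), n = lambda_mat.ncol();
  NumericMatrix out(np, m_max + 1);
  std::vector<double> cur(n);
  for (int r = 0; r < np; ++r) {
    for (int i = 0; i < n; ++i) cur[i] = std::exp(-lambda_mat(r, i));
    for (int m = 0; m <= m_max; ++m) {
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += w[i] * cur[i];
      out(r, m) = acc;
      if (m < m_max)
        for (int i = 0; i < n; ++i) cur[i] *= lambda_mat(r, i) / (m + 1.0);
    }
  }
  return out;
}

// Exact stochastic simulation of the two-state transcription network
//   OFF -> ON (theta_on), ON -> OFF (theta_off),
//   ON  -> ON + mRNA (theta_t), mRNA -> 0 (rate m, theta_d = 1).
// Each of n_cells cells is simulated independently for t_end time
// units from (OFF, 0) and its final mRNA count recorded.  Used as an
// independent oracle for the stationary distribution; uses R's RNG so
// set.seed() upstream makes it reproducible.
// [[Rcpp::export(name = ".gillespie_counts")]]
IntegerVector gillespie_counts(double theta_on, double theta_off,
                               double theta_t, int n_cells, double t_end) {
  IntegerVector out(n_cells);
  for (int c = 0; c < n_cells; ++c) {
    double t = 0.0;
    int on = 0, m = 0;
    while (true) {
      double a1 = on ? 0.0 : theta_on;
      double a2 = on ? theta_off : 0.0;
      double a3 = on ? theta_t : 0.0;
      double a4 = (double)m;
      double a0 = a1 + a2 + a3 + a4;
      t += R::rexp(1.0 / a0);
      if (t > t_end) break;
      double u = R::runif(0.0, a0);
      if (u < a1) on = 1;
      else if (u < a1 + a2) on = 0;
      else if (u < a1 + a2 + a3) ++m;
      else --m;
    }
    out[c] = m;
  }
  return out;
}

// Per-cell log-likelihood under each cluster's fitted parameters.
// counts: cells x genes integer matrix; logp: n_grid x (m_max+1) log-PMF
// cache; fit_idx: genes x K 1-based grid row per (gene, cluster).
// Returns cells x K.
// [[Rcpp::export(name = ".cell_cluster_loglik")]]
NumericMatrix cell_cluster_loglik(IntegerMatrix counts, NumericMatrix logp,
                                  IntegerMatrix fit_idx) {
  const int n = counts.nrow(), g = counts.ncol(), k = fit_idx.ncol();
  NumericMatrix out(n, k);
  for (int kk = 0; kk < k; ++kk)
    for (int gg = 0; gg < g; ++gg) {
      const int row = fit_idx(gg, kk) - 1;
      for (int cc = 0; cc < n; ++cc)
        out(cc, kk) += logp(row, counts(cc, gg));
    }
  return out;
}
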