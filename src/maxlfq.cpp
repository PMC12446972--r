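#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// median of a small vector (modified in place)
static double med(std::vector<double> &v) {
  std::size_t n = v.size();
  std::size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = 0.5 * (m + lo);
  }
  return m;
}

static int findRoot(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// MaxLFQ-style roll-up for one protein group.
// X: peptides x samples matrix of log2 intensities, NA = missing.
// For every sample pair sharing >= min_shared peptides the median pairwise
// log-ratio is computed; sample values v minimise
// sum over pairs (v_i - v_j - r_ij)^2 within each connected component, and
// each component is anchored so that the mean of v over its samples equals
// the mean over those samples of the per-sample mean observed intensity.
// Samples with no observed peptide get NA.
// [[Rcpp::export]]
NumericVector maxlfq_solve(NumericMatrix X, int min_shared = 1) {
  const int p = X.nrow(), n = X.ncol();
  NumericVector out(n, NA_REAL);

  std::vector<double> sampMean(n, 0.0);
  std::vector<int> sampCount(n, 0);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < p; ++i) {
      double x = X(i, j);
      if (!ISNAN(x)) { sampMean[j] += x; sampCount[j]++; }
    }
    if (sampCount[j] > 0) sampMean[j] /= sampCount[j];
  }

  arma::mat L(n, n, arma::fill::zeros);
  arma::vec b(n, arma::fill::zeros);
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;

  std::vector<double> diffs;
  for (int i = 0; i < n; ++i) {
    if (sampCount[i] == 0) continue;
    for (int j = i + 1; j < n; ++j) {
      if (sampCount[j] == 0) continue;
      diffs.clear();
      for (int k = 0; k < p; ++k) {
        double xi = X(k, i), xj = X(k, j);
        if (!ISNAN(xi) && !ISNAN(xj)) diffs.push_back(xi - xj);
      }
      if ((int)diffs.size() < min_shared || diffs.empty()) continue;
      double r = med(diffs);
      L(i, i) += 1.0; L(j, j) += 1.0;
      L(i, j) -= 1.0; L(j, i) -= 1.0;
      b(i) += r;      b(j) -= r;
      parent[findRoot(parent, i)] = findRoot(parent, j);
    }
  }

  // group samples with data by component root
  std::map<int, std::vector<int> > comps;
  for (int i = 0; i < n; ++i)
    if (sampCount[i] > 0) comps[findRoot(parent, i)].push_back(i);

  for (std::map<int, std::vector<int> >::iterator it = comps.begin();
       it != comps.end(); ++it) {
    const std::vector<int> &idx = it->second;
    const int m = (int)idx.size();
    double anchor = 0.0;
    for (int k = 0; k < m; ++k) anchor += sampMean[idx[k]];
    anchor /= m;
    if (m == 1) { out[idx[0]] = anchor; continue; }
    arma::uvec ui(m);
    for (int k = 0; k < m; ++k) ui(k) = idx[k];
    arma::mat Lc = L.submat(ui, ui);
    arma::vec bc = b.elem(ui);
    // the Laplacian is singular with nullspace = constants and bc sums to
    // zero within the component, so adding a rank-one term (1/m) J makes
    // the system invertible and returns the mean-zero least-squares
    // solution; then shift to the anchor
    Lc += arma::ones(m, m) / (double)m;
    arma::vec v;
    bool ok = arma::solve(v, Lc, bc, arma::solve_opts::likely_sympd);
    if (!ok) v = arma::pinv(L.submat(ui, ui)) * bc;
    double shift = anchor - arma::mean(v);
    for (int k = 0; k < m; ++k) out[idx[k]] = v(k) + shift;
  }
  return out;
}
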