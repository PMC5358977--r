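#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping with squared local cost and symmetric unit steps
// (match / insert / delete). The returned dissimilarity is the minimum over
// all monotone boundary-to-boundary warping paths of
//   (sum of squared frequency differences along the path) / (path length),
// i.e. the mean squared error of the best alignment. Direct DP minimises a
// path sum, not a ratio, so the ratio is minimised exactly by Dinkelbach
// iteration: for a level lambda, the DP on cost(i,j) - lambda has optimal
// value 0 iff lambda is the optimal ratio; each iteration re-solves the DP
// at the ratio of the current argmin path and converges after a handful of
// passes (the path set is finite).

struct PathStat { double sum; int len; };

// Fill the cumulative DP matrix for cost(i,j) - lambda, then backtrack the
// argmin path to recover its raw cost sum and length. V is a caller-owned
// scratch buffer of size >= n*m.
static PathStat dtw_pass(const double* a, int n, const double* b, int m,
                         double lambda, std::vector<double>& V) {
  double* row = V.data();
  {
    double d = a[0] - b[0];
    row[0] = d * d - lambda;
    for (int j = 1; j < m; ++j) {
      double dj = a[0] - b[j];
      row[j] = row[j - 1] + dj * dj - lambda;
    }
  }
  for (int i = 1; i < n; ++i) {
    const double* prev = V.data() + (size_t)(i - 1) * m;
    double* cur = V.data() + (size_t)i * m;
    double d0 = a[i] - b[0];
    cur[0] = prev[0] + d0 * d0 - lambda;
    for (int j = 1; j < m; ++j) {
      double d = a[i] - b[j];
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = best + d * d - lambda;
    }
  }
  // backtrack (diagonal preferred on exact ties)
  int i = n - 1, j = m - 1, len = 1;
  double d = a[i] - b[j];
  double sum = d * d;
  while (i > 0 || j > 0) {
    int pi = i, pj = j;
    if (i > 0 && j > 0) {
      double vd = V[(size_t)(i - 1) * m + (j - 1)];
      double vu = V[(size_t)(i - 1) * m + j];
      double vl = V[(size_t)i * m + (j - 1)];
      if (vd <= vu && vd <= vl) { pi = i - 1; pj = j - 1; }
      else if (vu <= vl) { pi = i - 1; }
      else { pj = j - 1; }
    } else if (i > 0) { pi = i - 1; } else { pj = j - 1; }
    i = pi; j = pj;
    d = a[i] - b[j];
    sum += d * d;
    ++len;
  }
  return PathStat{sum, len};
}

static double dtw_mse_raw(const double* a, int n, const double* b, int m,
                          std::vector<double>& V) {
  if ((size_t)n * m > V.size()) V.resize((size_t)n * m);
  // initial feasible ratio: the minimum-sum path
  PathStat ps = dtw_pass(a, n, b, m, 0.0, V);
  double lambda = ps.sum / ps.len;
  for (int it = 0; it < 64; ++it) {
    ps = dtw_pass(a, n, b, m, lambda, V);
    double ratio = ps.sum / ps.len;          // <= lambda by construction
    double g = ps.sum - lambda * ps.len;     // <= 0; 0 iff lambda optimal
    if (g >= -1e-12 * (1.0 + std::abs(ps.sum))) return ratio;
    lambda = ratio;
  }
  return lambda;
}

// [[Rcpp::export]]
double dtw_mse_cpp(NumericVector a, NumericVector b) {
  if (a.size() < 2 || b.size() < 2)
    stop("DTW requires contours of length >= 2");
  std::vector<double> V;
  return dtw_mse_raw(a.begin(), a.size(), b.begin(), b.size(), V);
}

// [[Rcpp::export]]
NumericMatrix dtw_all_pairs_cpp(List contours) {
  int n = contours.size();
  std::vector<NumericVector> keep(n);
  std::vector<const double*> v(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) {
    keep[i] = as<NumericVector>(contours[i]);
    if (keep[i].size() < 2) stop("DTW requires contours of length >= 2");
    v[i] = keep[i].begin();
    len[i] = keep[i].size();
  }
  NumericMatrix D(n, n);
  std::vector<double> V;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = dtw_mse_raw(v[i], len[i], v[j], len[j], V);
      D(i, j) = d; D(j, i) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return D;
}
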