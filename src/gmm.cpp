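#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Univariate Gaussian-mixture fits (1..kmax components) per grid cell to
// the bootstrap distribution of density values, selected by AIC. EM with
// deterministic quantile initialisation (no RNG), so fits are reproducible
// given the bootstrap sample. Cells whose bootstrap values are (nearly)
// constant are represented as point masses (sd = 0, one component).

static const double SQRT2PI = 2.5066282746310002;

// single-precision exponential: EM responsibilities and likelihood sums do
// not need more than ~1e-7 relative accuracy, and expf is markedly faster
static inline double fexp(double x) {
  if (x < -87.0) return 0.0;
  return (double)expf((float)x);
}

static double mix_loglik(const std::vector<double>& x,
                         const std::vector<double>& w,
                         const std::vector<double>& mu,
                         const std::vector<double>& sd) {
  int k = w.size();
  double ll = 0.0;
  for (double xi : x) {
    double s = 0.0;
    for (int c = 0; c < k; ++c) {
      double z = (xi - mu[c]) / sd[c];
      s += w[c] * fexp(-0.5 * z * z) / (sd[c] * SQRT2PI);
    }
    ll += std::log(s > 1e-300 ? s : 1e-300);
  }
  return ll;
}

// EM fit with k components; returns log-likelihood, params by reference.
static double em_fit(const std::vector<double>& xs,  // sorted copy
                     int k, int max_iter, double tol, double sd_floor,
                     std::vector<double>& w, std::vector<double>& mu,
                     std::vector<double>& sd) {
  int n = xs.size();
  w.assign(k, 1.0 / k); mu.resize(k); sd.resize(k);
  double m0 = 0, v0 = 0;
  for (double v : xs) m0 += v; m0 /= n;
  for (double v : xs) v0 += (v - m0) * (v - m0); v0 /= n;
  double s0 = std::sqrt(v0);
  if (k == 1) {
    // single Gaussian: the MLE is closed form, no EM needed
    w[0] = 1.0; mu[0] = m0; sd[0] = std::max(s0, sd_floor);
    return mix_loglik(xs, w, mu, sd);
  }
  for (int c = 0; c < k; ++c) {
    int idx = (int)std::floor(n * (2.0 * c + 1) / (2.0 * k));
    if (idx > n - 1) idx = n - 1;
    mu[c] = xs[idx];
    sd[c] = std::max(s0 / k, sd_floor);
  }
  std::vector<double> resp(n * k);
  std::vector<double> cf(k), isd(k), nk(k), mk(k), vk(k);
  double ll = -1e300;
  for (int it = 0; it < max_iter; ++it) {
    for (int c = 0; c < k; ++c) {
      isd[c] = 1.0 / sd[c];
      cf[c] = w[c] * isd[c] / SQRT2PI;
      nk[c] = mk[c] = 0.0;
    }
    // E step (responsibilities) with fused zeroth/first-moment accumulation
    double llnew = 0.0;
    for (int i = 0; i < n; ++i) {
      const double x = xs[i];
      double tot = 0.0;
      double* r = &resp[(size_t)i * k];
      for (int c = 0; c < k; ++c) {
        double z = (x - mu[c]) * isd[c];
        double d = cf[c] * fexp(-0.5 * z * z);
        r[c] = d; tot += d;
      }
      if (tot < 1e-300) tot = 1e-300;
      const double itot = 1.0 / tot;
      for (int c = 0; c < k; ++c) {
        r[c] *= itot;
        nk[c] += r[c];
        mk[c] += r[c] * x;
      }
      llnew += std::log(tot);
    }
    // M step: means from the fused pass, variances in one more pass
    for (int c = 0; c < k; ++c) {
      if (nk[c] < 1e-10) nk[c] = 1e-10;
      mk[c] /= nk[c];
      vk[c] = 0.0;
    }
    for (int i = 0; i < n; ++i) {
      const double x = xs[i];
      const double* r = &resp[(size_t)i * k];
      for (int c = 0; c < k; ++c) {
        double d = x - mk[c];
        vk[c] += r[c] * d * d;
      }
    }
    for (int c = 0; c < k; ++c) {
      w[c] = nk[c] / n; mu[c] = mk[c];
      sd[c] = std::max(std::sqrt(vk[c] / nk[c]), sd_floor);
    }
    if (std::abs(llnew - ll) < tol * (1.0 + std::abs(llnew))) { ll = llnew; break; }
    ll = llnew;
  }
  return mix_loglik(xs, w, mu, sd);
}

// [[Rcpp::export]]
List gmm_fit_cells_cpp(NumericMatrix X, int kmax = 3, int max_iter = 15,
                       double tol = 1e-5) {
  int n = X.nrow(), ncell = X.ncol();
  NumericMatrix W(kmax, ncell), MU(kmax, ncell), SD(kmax, ncell);
  IntegerVector K(ncell);
  for (int j = 0; j < ncell; ++j) {
    std::vector<double> xs(n);
    for (int i = 0; i < n; ++i) xs[i] = X(i, j);
    std::sort(xs.begin(), xs.end());
    double m0 = 0; for (double v : xs) m0 += v; m0 /= n;
    double v0 = 0; for (double v : xs) v0 += (v - m0) * (v - m0); v0 /= n;
    double scale = std::max(std::abs(m0), std::sqrt(v0));
    if (std::sqrt(v0) <= 1e-9 * (scale > 0 ? scale : 1.0)) {
      // degenerate cell: point mass at the common value
      K[j] = 1; W(0, j) = 1.0; MU(0, j) = m0; SD(0, j) = 0.0;
      continue;
    }
    double sd_floor = 1e-4 * std::sqrt(v0);
    double best_aic = R_PosInf;
    std::vector<double> bw, bmu, bsd;
    int bk = 1;
    for (int k = 1; k <= kmax && k <= n; ++k) {
      std::vector<double> w, mu, sd;
      double ll = em_fit(xs, k, max_iter, tol, sd_floor, w, mu, sd);
      double aic = 2.0 * (3 * k - 1) - 2.0 * ll;
      if (aic < best_aic) { best_aic = aic; bk = k; bw = w; bmu = mu; bsd = sd; }
    }
    K[j] = bk;
    for (int c = 0; c < bk; ++c) { W(c, j) = bw[c]; MU(c, j) = bmu[c]; SD(c, j) = bsd[c]; }
  }
  return List::create(_["k"] = K, _["w"] = W, _["mu"] = MU, _["sd"] = SD);
}

static double mix_cdf(double x, int k, const double* w, const double* mu,
                      const double* sd) {
  double F = 0.0;
  for (int c = 0; c < k; ++c) {
    if (sd[c] <= 0) F += w[c] * (x >= mu[c] ? 1.0 : 0.0);
    else F += w[c] * R::pnorm(x, mu[c], sd[c], 1, 0);
  }
  return F;
}

static double mix_pdf(double x, int k, const double* w, const double* mu,
                      const double* sd) {
  double f = 0.0;
  for (int c = 0; c < k; ++c)
    if (sd[c] > 0) f += w[c] * R::dnorm(x, mu[c], sd[c], 0);
  return f;
}

// P(X_ht > X_wt) for independent mixtures, cell by cell. Continuous vs
// continuous: trapezoidal integration of q_wt(v) * (1 - F_ht(v)) on a grid
// spanning both mixtures' 1e-6 .. 1-1e-6 quantile envelopes. Point masses
// are handled analytically.
// [[Rcpp::export]]
NumericVector pht_cells_cpp(List fit_wt, List fit_ht, int ngrid = 2048) {
  IntegerVector kw = fit_wt["k"], kh = fit_ht["k"];
  NumericMatrix Ww = fit_wt["w"], MUw = fit_wt["mu"], SDw = fit_wt["sd"];
  NumericMatrix Wh = fit_ht["w"], MUh = fit_ht["mu"], SDh = fit_ht["sd"];
  int ncell = kw.size();
  if (kh.size() != ncell) stop("cell-model grids do not match");
  NumericVector out(ncell);
  const double zq = R::qnorm(1e-6, 0.0, 1.0, 1, 0);  // ~ -4.75

  // cells below a group's numerical support floor carry a `tiny` flag;
  // where both groups are below floor the densities are indistinguishable
  // from zero and no direction is supported
  LogicalVector tw = fit_wt.containsElementNamed("tiny") ?
      as<LogicalVector>(fit_wt["tiny"]) : LogicalVector(ncell);
  LogicalVector th = fit_ht.containsElementNamed("tiny") ?
      as<LogicalVector>(fit_ht["tiny"]) : LogicalVector(ncell);

  for (int j = 0; j < ncell; ++j) {
    if (tw[j] && th[j]) { out[j] = 0.5; continue; }
    int kwj = kw[j], khj = kh[j];
    const double *ww = &Ww(0, j), *mw = &MUw(0, j), *sw = &SDw(0, j);
    const double *wh = &Wh(0, j), *mh = &MUh(0, j), *sh = &SDh(0, j);
    bool wt_point = true, ht_point = true;
    for (int c = 0; c < kwj; ++c) if (sw[c] > 0) wt_point = false;
    for (int c = 0; c < khj; ++c) if (sh[c] > 0) ht_point = false;

    if (wt_point && ht_point) {
      // compare the (possibly multi-atom) point masses pairwise
      double p = 0.0;
      for (int a = 0; a < khj; ++a)
        for (int b = 0; b < kwj; ++b) {
          if (mh[a] > mw[b]) p += wh[a] * ww[b];
          else if (mh[a] == mw[b]) p += 0.5 * wh[a] * ww[b];
        }
      out[j] = p;
      continue;
    }
    if (wt_point) {           // P(HT > wt_atom)
      double p = 0.0;
      for (int b = 0; b < kwj; ++b)
        p += ww[b] * (1.0 - mix_cdf(mw[b], khj, wh, mh, sh));
      out[j] = p;
      continue;
    }
    if (ht_point) {           // P(ht_atom > WT)
      double p = 0.0;
      for (int a = 0; a < khj; ++a)
        p += wh[a] * mix_cdf(mh[a], kwj, ww, mw, sw);
      out[j] = p;
      continue;
    }

    double lo = R_PosInf, hi = R_NegInf;
    for (int c = 0; c < kwj; ++c) {
      lo = std::min(lo, mw[c] + zq * sw[c]);
      hi = std::max(hi, mw[c] - zq * sw[c]);
    }
    for (int c = 0; c < khj; ++c) {
      lo = std::min(lo, mh[c] + zq * sh[c]);
      hi = std::max(hi, mh[c] - zq * sh[c]);
    }
    double h = (hi - lo) / (ngrid - 1);
    double acc = 0.0;
    double prev = mix_pdf(lo, kwj, ww, mw, sw) *
                  (1.0 - mix_cdf(lo, khj, wh, mh, sh));
    for (int i = 1; i < ngrid; ++i) {
      double v = lo + h * i;
      double cur = mix_pdf(v, kwj, ww, mw, sw) *
                   (1.0 - mix_cdf(v, khj, wh, mh, sh));
      acc += 0.5 * (prev + cur) * h;
      prev = cur;
    }
    out[j] = std::min(1.0, std::max(0.0, acc));
  }
  return out;
}
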