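#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact t-SNE gradient descent on a precomputed joint-probability matrix P
// (symmetric, entries summing to 1). Student-t kernel in the embedding,
// early exaggeration, momentum switch, and adaptive per-coordinate gains as
// in the reference implementation. All pairwise quantities are accumulated
// in symmetric half-loops without materialising n x n temporaries.
// Terminates when the relative change of the KL cost between successive
// checks (every `check_every` iterations, once exaggeration has ended)
// falls below `tol`.

// [[Rcpp::export]]
List tsne_cpp(NumericMatrix P, NumericMatrix Y0, int max_iter, double tol,
              double eta, double exaggeration, int exag_end,
              double momentum_init, double momentum_final, int mom_switch,
              int check_every) {
  const int n = P.nrow();
  const double pmin = 1e-12;
  std::vector<double> yx(n), yy(n), dx(n), dy(n), ix(n, 0.0), iy(n, 0.0),
      gx(n, 1.0), gy(n, 1.0);
  for (int i = 0; i < n; ++i) { yx[i] = Y0(i, 0); yy[i] = Y0(i, 1); }

  double prev_cost = R_PosInf, cost = R_PosInf;
  int iter_done = max_iter;

  for (int iter = 0; iter < max_iter; ++iter) {
    const bool exag = iter < exag_end;
    const double pfac = exag ? exaggeration : 1.0;
    const bool want_cost =
        !exag && ((iter + 1) % check_every == 0 || iter == max_iter - 1);

    // pass 1: normalisation constant of the Student-t kernel
    double Z = 0.0;
    for (int j = 1; j < n; ++j) {
      const double xj = yx[j], yj = yy[j];
      for (int i = 0; i < j; ++i) {
        double ddx = yx[i] - xj, ddy = yy[i] - yj;
        Z += 1.0 / (1.0 + ddx * ddx + ddy * ddy);
      }
    }
    Z *= 2.0;
    if (Z < 1e-300) Z = 1e-300;

    // pass 2: gradient (and KL cost when checking)
    std::fill(dx.begin(), dx.end(), 0.0);
    std::fill(dy.begin(), dy.end(), 0.0);
    double kl = 0.0;
    for (int j = 1; j < n; ++j) {
      const double xj = yx[j], yj = yy[j];
      const double* Pcol = &P(0, j);
      for (int i = 0; i < j; ++i) {
        double ddx = yx[i] - xj, ddy = yy[i] - yj;
        double num = 1.0 / (1.0 + ddx * ddx + ddy * ddy);
        double p = Pcol[i] < pmin ? pmin : Pcol[i];
        double mult = (pfac * p - num / Z) * num;
        double cx = mult * ddx, cy = mult * ddy;
        dx[i] += cx; dy[i] += cy;
        dx[j] -= cx; dy[j] -= cy;
        if (want_cost) {
          double q = num / Z; if (q < pmin) q = pmin;
          kl += 2.0 * p * std::log(p / q);
        }
      }
    }

    const double momentum = iter < mom_switch ? momentum_init : momentum_final;
    double mx = 0.0, my = 0.0;
    for (int i = 0; i < n; ++i) {
      double gdx = 4.0 * dx[i], gdy = 4.0 * dy[i];
      gx[i] = ((gdx > 0) == (ix[i] > 0)) ? gx[i] * 0.8 : gx[i] + 0.2;
      gy[i] = ((gdy > 0) == (iy[i] > 0)) ? gy[i] * 0.8 : gy[i] + 0.2;
      if (gx[i] < 0.01) gx[i] = 0.01;
      if (gy[i] < 0.01) gy[i] = 0.01;
      ix[i] = momentum * ix[i] - eta * gx[i] * gdx;
      iy[i] = momentum * iy[i] - eta * gy[i] * gdy;
      yx[i] += ix[i]; yy[i] += iy[i];
      mx += yx[i]; my += yy[i];
    }
    mx /= n; my /= n;
    for (int i = 0; i < n; ++i) { yx[i] -= mx; yy[i] -= my; }

    if (want_cost) {
      cost = kl;
      if (std::isfinite(prev_cost) &&
          std::abs(prev_cost - cost) / std::abs(prev_cost) < tol) {
        iter_done = iter + 1;
        break;
      }
      prev_cost = cost;
    }
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix Y(n, 2);
  for (int i = 0; i < n; ++i) { Y(i, 0) = yx[i]; Y(i, 1) = yy[i]; }
  return List::create(_["Y"] = Y, _["cost"] = cost, _["iter"] = iter_done);
}
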