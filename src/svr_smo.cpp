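// SMO solver for the epsilon-insensitive SVR dual (LIBSVM-style working
// set selection on the 2n-variable formulation).
//
//   min_a  0.5 a' Q a + p' a   s.t.  z' a = 0,  0 <= a_t <= C
//
// with t = 1..2n, z_t = +1 for t <= n (alpha) and -1 otherwise (alpha*),
// Q_st = z_s z_t K(s mod n, t mod n), p_t = eps - y_i (t <= n) or
// eps + y_i (t > n).  Returns beta = alpha - alpha* and the bias b.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".svr_smo")]]
List svr_smo(NumericMatrix K, NumericVector y, double C, double eps,
             double tol = 1e-3, int max_iter = 200000) {
  const int n = y.size();
  const int N = 2 * n;
  std::vector<double> a(N, 0.0), G(N), z(N);
  for (int t = 0; t < N; ++t) {
    const int i = t % n;
    z[t] = (t < n) ? 1.0 : -1.0;
    G[t] = (t < n) ? (eps - y[i]) : (eps + y[i]);
  }

  bool converged = false;
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // second-order working-set selection: i maximizes the violation,
    // j maximizes the guaranteed objective decrease against i
    int ti = -1, tj = -1;
    double gmax = -HUGE_VAL, gmin = HUGE_VAL;
    for (int t = 0; t < N; ++t) {
      const double v = -z[t] * G[t];
      const bool up = (z[t] > 0 && a[t] < C) || (z[t] < 0 && a[t] > 0);
      const bool lo = (z[t] > 0 && a[t] > 0) || (z[t] < 0 && a[t] < C);
      if (up && v > gmax) { gmax = v; ti = t; }
      if (lo && v < gmin) gmin = v;
    }
    if (ti < 0 || gmax - gmin < tol) { converged = true; break; }

    const int ii = ti % n;
    double best_dec = 0.0;
    for (int t = 0; t < N; ++t) {
      const bool lo = (z[t] > 0 && a[t] > 0) || (z[t] < 0 && a[t] < C);
      if (!lo) continue;
      const double b_it = gmax - (-z[t] * G[t]);
      if (b_it <= 0) continue;
      const double a_it =
          std::max(K(ii, ii) + K(t % n, t % n) - 2.0 * K(ii, t % n), 1e-12);
      const double dec = b_it * b_it / a_it;
      if (dec > best_dec) { best_dec = dec; tj = t; }
    }
    if (tj < 0) { converged = true; break; }

    const int jj = tj % n;
    // curvature along the feasible pair direction; the z factors cancel
    // (Q_st = z_s z_t K and the step is Da_i = z_i d, Da_j = -z_j d)
    const double quad =
        std::max(K(ii, ii) + K(jj, jj) - 2.0 * K(ii, jj), 1e-12);
    double delta = (z[tj] * G[tj] - z[ti] * G[ti]) / quad;

    double lo_d, hi_d;
    if (z[ti] > 0) { lo_d = -a[ti]; hi_d = C - a[ti]; }
    else           { lo_d = a[ti] - C; hi_d = a[ti]; }
    if (z[tj] > 0) { lo_d = std::max(lo_d, a[tj] - C); hi_d = std::min(hi_d, a[tj]); }
    else           { lo_d = std::max(lo_d, -a[tj]);    hi_d = std::min(hi_d, C - a[tj]); }
    delta = std::min(std::max(delta, lo_d), hi_d);
    if (delta == 0.0) { converged = true; break; }

    a[ti] += z[ti] * delta;
    a[tj] -= z[tj] * delta;
    for (int t = 0; t < N; ++t) {
      const int q = t % n;
      G[t] += z[t] * delta * (K(q, ii) - K(q, jj));
    }
  }

  // bias from the KKT conditions: -z G equals b on free variables
  double b, gmax = -HUGE_VAL, gmin = HUGE_VAL, free_sum = 0.0;
  int n_free = 0;
  for (int t = 0; t < N; ++t) {
    const double v = -z[t] * G[t];
    const bool up = (z[t] > 0 && a[t] < C) || (z[t] < 0 && a[t] > 0);
    const bool lo = (z[t] > 0 && a[t] > 0) || (z[t] < 0 && a[t] < C);
    if (up && v > gmax) gmax = v;
    if (lo && v < gmin) gmin = v;
    if (a[t] > 0 && a[t] < C) { free_sum += v; ++n_free; }
  }
  b = (n_free > 0) ? free_sum / n_free : (gmax + gmin) / 2.0;

  NumericVector beta(n);
  for (int i = 0; i < n; ++i) beta[i] = a[i] - a[i + n];
  return List::create(_["beta"] = beta, _["b"] = b,
                      _["iterations"] = iter, _["converged"] = converged);
}
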