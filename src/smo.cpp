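// Sequential minimal optimisation for the soft-margin SVM dual with a
// precomputed kernel matrix and per-sample box constraints (class weights).
//
// Solves  min_a 0.5 a'Qa - e'a,  0 <= a_i <= C_i,  y'a = 0,
// with Q_ij = y_i y_j K_ij, by maximal-violating-pair working-set
// selection. Returns alpha and the offset rho so that the decision value is
// f(x) = sum_i y_i a_i K(x_i, x) - rho.

#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, NumericVector C,
               double tol = 1e-3, int max_iter = 0) {
  const int n = K.nrow();
  if (max_iter <= 0) max_iter = std::max(10000000 / std::max(n, 1), 100 * n);

  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  auto Q = [&](int i, int j) { return y[i] * y[j] * K(i, j); };

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // working-set selection: maximal violating pair
    double Gmax = -DBL_MAX, Gmax2 = -DBL_MAX;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      if (y[t] > 0) {
        if (alpha[t] < C[t] && -G[t] > Gmax) { Gmax = -G[t]; i = t; }
        if (alpha[t] > 0 && G[t] > Gmax2) { Gmax2 = G[t]; j = t; }
      } else {
        if (alpha[t] > 0 && G[t] > Gmax) { Gmax = G[t]; i = t; }
        if (alpha[t] < C[t] && -G[t] > Gmax2) { Gmax2 = -G[t]; j = t; }
      }
    }
    if (i < 0 || j < 0 || Gmax + Gmax2 < tol) break;

    double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      double quad = Q(i, i) + Q(j, j) + 2.0 * Q(i, j);
      if (quad <= 0) quad = 1e-12;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > C[i] - C[j]) {
        if (alpha[i] > C[i]) { alpha[i] = C[i]; alpha[j] = C[i] - diff; }
      } else {
        if (alpha[j] > C[j]) { alpha[j] = C[j]; alpha[i] = C[j] + diff; }
      }
    } else {
      double quad = Q(i, i) + Q(j, j) - 2.0 * Q(i, j);
      if (quad <= 0) quad = 1e-12;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C[i]) {
        if (alpha[i] > C[i]) { alpha[i] = C[i]; alpha[j] = sum - C[i]; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C[j]) {
        if (alpha[j] > C[j]) { alpha[j] = C[j]; alpha[i] = sum - C[j]; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai == 0.0 && daj == 0.0) break;
    for (int t = 0; t < n; ++t)
      G[t] += Q(t, i) * dai + Q(t, j) * daj;
  }

  // offset rho from the KKT conditions
  double ub = DBL_MAX, lb = -DBL_MAX, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] >= C[t] - 1e-12) {
      if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-12) {
      if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++n_free; sum_free += yG;
    }
  }
  double rho = (n_free > 0) ? sum_free / n_free : (ub + lb) / 2.0;

  // 0.5 a'Qa - e'a = 0.5 sum_t a_t (G_t - 1), since G = Qa - e
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += 0.5 * alpha[t] * (G[t] - 1.0);

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho,
                      _["objective"] = obj,
                      _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}
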