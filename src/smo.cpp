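#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the epsilon-insensitive SVR dual.
//
// The dual is expressed over z = (alpha, alpha*) in [0, C]^{2l} with signs
// s_t = -1 for the alpha block and +1 for the alpha* block, so that
// beta = alpha* - alpha and the problem becomes a classification-shaped
// box QP: minimise (1/2) z' Q z + p' z with Q_{tt'} = s_t s_t' K_{tt'},
// p_t = eps - s_t y_t, subject to sum_t s_t z_t = 0.
//
// Pair selection is maximal-violating-pair on the first index and
// second-order (maximal objective decrease) on the partner, as in modern
// SMO solvers. Convergence is declared when the KKT violation gap
// max_{I_up}(-s grad) - min_{I_low}(-s grad) drops below `tol`.
// K is symmetric, so all kernel reads go through contiguous columns.

// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double eps_tube,
               double tol, int max_iter) {
  const int l = y.size(), m = 2 * l;
  std::vector<double> z(m, 0.0), grad(m), diag(l);
  const double *Kp = K.begin();
  for (int i = 0; i < l; ++i) diag[i] = Kp[(R_xlen_t)i * l + i];
  for (int t = 0; t < m; ++t) {
    const double s = t < l ? -1.0 : 1.0;
    grad[t] = eps_tube - s * y[t % l];
  }

  int iter = 0;
  double gap = R_PosInf;
  for (iter = 0; iter < max_iter; ++iter) {
    int ii = -1;
    double up = R_NegInf, lo = R_PosInf;
    for (int t = 0; t < m; ++t) {
      const double s = t < l ? -1.0 : 1.0, v = -s * grad[t];
      const bool in_up  = (s > 0) ? (z[t] < C) : (z[t] > 0);
      const bool in_low = (s > 0) ? (z[t] > 0) : (z[t] < C);
      if (in_up && v > up)  { up = v; ii = t; }
      if (in_low && v < lo) lo = v;
    }
    if (ii < 0 || lo == R_PosInf) { gap = 0.0; break; }
    gap = up - lo;
    if (gap <= tol) break;

    const int i0 = ii % l;
    const double si = ii < l ? -1.0 : 1.0;
    const double *Ki = Kp + (R_xlen_t)i0 * l;  // column i0 (== row, symmetric)
    const double dii = diag[i0];
    int jj = -1;
    double best = -1.0;
    for (int t = 0; t < m; ++t) {
      const double s = t < l ? -1.0 : 1.0, v = -s * grad[t];
      const bool in_low = (s > 0) ? (z[t] > 0) : (z[t] < C);
      if (!in_low || v >= up) continue;
      const int t0 = t % l;
      double a = dii + diag[t0] - 2.0 * Ki[t0];
      if (a < 1e-12) a = 1e-12;
      const double d = up - v, gain = d * d / a;
      if (gain > best) { best = gain; jj = t; }
    }
    if (jj < 0) { gap = 0.0; break; }

    const int j0 = jj % l;
    const double sj = jj < l ? -1.0 : 1.0;
    const double *Kj = Kp + (R_xlen_t)j0 * l;
    double a = dii + diag[j0] - 2.0 * Ki[j0];
    if (a < 1e-12) a = 1e-12;
    // move z_ii by s_i*delta and z_jj by -s_j*delta: preserves the
    // equality constraint exactly and decreases the objective
    double delta = (up - (-sj * grad[jj])) / a;
    const double di_max = si > 0 ? C - z[ii] : z[ii];
    const double dj_max = sj > 0 ? z[jj] : C - z[jj];
    if (delta > di_max) delta = di_max;
    if (delta > dj_max) delta = dj_max;
    z[ii] += si * delta;
    z[jj] -= sj * delta;
    if (z[ii] < 0) z[ii] = 0;
    if (z[ii] > C) z[ii] = C;
    if (z[jj] < 0) z[jj] = 0;
    if (z[jj] > C) z[jj] = C;
    for (int t = 0; t < l; ++t) {
      const double dk = delta * (Ki[t] - Kj[t]);
      grad[t] -= dk;      // alpha block, s = -1
      grad[l + t] += dk;  // alpha* block, s = +1
    }
  }

  // bias: -s grad is pinned to b at every unbounded dual variable;
  // fall back to the midpoint of the KKT-feasible interval [up, lo]
  double bsum = 0.0, up = R_NegInf, lo = R_PosInf;
  int bn = 0;
  for (int t = 0; t < m; ++t) {
    const double s = t < l ? -1.0 : 1.0, v = -s * grad[t];
    const bool in_up  = (s > 0) ? (z[t] < C) : (z[t] > 0);
    const bool in_low = (s > 0) ? (z[t] > 0) : (z[t] < C);
    if (in_up && v > up)  up = v;
    if (in_low && v < lo) lo = v;
    if (z[t] > 1e-10 * C && z[t] < C * (1.0 - 1e-10)) { bsum += v; ++bn; }
  }
  const double b = bn > 0 ? bsum / bn : (up + lo) / 2.0;

  NumericVector beta(l);
  for (int i = 0; i < l; ++i) beta[i] = z[l + i] - z[i];
  double obj = 0.0;
  for (int i = 0; i < l; ++i) {
    double ki = 0.0;
    const double *Kc = Kp + (R_xlen_t)i * l;
    for (int j = 0; j < l; ++j) ki += Kc[j] * beta[j];
    obj += 0.5 * beta[i] * ki + eps_tube * (z[i] + z[l + i]) - y[i] * beta[i];
  }

  return List::create(_["beta"] = beta, _["bias"] = b,
                      _["gap"] = gap > 0 ? gap : 0.0, _["iterations"] = iter,
                      _["dual_objective"] = obj, _["n_unbounded"] = bn,
                      _["converged"] = gap <= tol);
}

// KKT violation gap of a given coefficient vector, reconstructing
// alpha = max(-beta, 0), alpha* = max(beta, 0) (complementary at optimum).

// [[Rcpp::export]]
double smo_kkt_gap(NumericMatrix K, NumericVector y, NumericVector beta,
                   double C, double eps_tube) {
  const int l = y.size();
  double up = R_NegInf, lo = R_PosInf;
  for (int i = 0; i < l; ++i) {
    double g = 0.0;
    for (int j = 0; j < l; ++j) g += K(i, j) * beta[j];
    const double za = beta[i] < 0 ? -beta[i] : 0.0;  // alpha
    const double zs = beta[i] > 0 ?  beta[i] : 0.0;  // alpha*
    // alpha block (s = -1): -s grad = -g + eps + y_i
    const double va = -g + eps_tube + y[i];
    if (za > 0 && va > up) up = va;
    if (za < C && va < lo) lo = va;
    // alpha* block (s = +1): -s grad = -(g + eps - y_i)
    const double vs = -(g + eps_tube - y[i]);
    if (zs < C && vs > up) up = vs;
    if (zs > 0 && vs < lo) lo = vs;
  }
  const double gap = up - lo;
  return gap > 0 ? gap : 0.0;
}
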