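// Euler core of the hybrid cybernetic simulator. The genetic-algorithm fit
// evaluates this trajectory thousands of times, so the step loop is compiled;
// all bookkeeping (families, validation, labels) stays in R.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".hcm_core")]]
NumericMatrix hcm_core(NumericVector k, NumericVector K, NumericVector beta,
                       NumericVector e0, NumericVector cw,
                       NumericMatrix Zmat, NumericVector Z_X,
                       IntegerVector pref_idx, NumericVector conc0,
                       double X0, int n, double dt, double dil_sign) {
  const int nf = k.size();
  const int nm = conc0.size();
  NumericMatrix out(n, 2 + nm + 4 * nf);
  std::vector<double> conc(conc0.begin(), conc0.end());
  std::vector<double> e(e0.begin(), e0.end());
  std::vector<double> sat(nf), kern(nf), R(nf), u(nf), v(nf), r(nf);
  double X = X0, mu_lag = 0.0;

  for (int i = 0; i < n; ++i) {
    double sumR = 0.0, maxR = 0.0;
    for (int j = 0; j < nf; ++j) {
      double m = conc[pref_idx[j] - 1];
      if (m < 0.0) m = 0.0;
      sat[j] = m / (K[j] + m);
      kern[j] = k[j] * sat[j] * e[j];
      R[j] = kern[j] * cw[j];
      sumR += R[j];
      if (R[j] > maxR) maxR = R[j];
    }
    if (sumR <= 0.0) {
      for (int j = 0; j < nf; ++j) { u[j] = 1.0 / nf; v[j] = 1.0; }
    } else {
      for (int j = 0; j < nf; ++j) { u[j] = R[j] / sumR; v[j] = R[j] / maxR; }
    }
    for (int j = 0; j < nf; ++j) r[j] = kern[j] * v[j];

    out(i, 0) = i * dt;
    out(i, 1) = X;
    for (int m = 0; m < nm; ++m) out(i, 2 + m) = conc[m];
    for (int j = 0; j < nf; ++j) {
      out(i, 2 + nm + j) = e[j];
      out(i, 2 + nm + nf + j) = u[j];
      out(i, 2 + nm + 2 * nf + j) = v[j];
      out(i, 2 + nm + 3 * nf + j) = r[j];
    }
    if (i == n - 1) break;

    double dX = 0.0;
    for (int j = 0; j < nf; ++j) dX += r[j] * Z_X[j];
    dX *= X;
    for (int m = 0; m < nm; ++m) {
      double dM = 0.0;
      for (int j = 0; j < nf; ++j) dM += r[j] * Zmat(j, m);
      conc[m] += dM * X * dt;
      if (conc[m] < 0.0) conc[m] = 0.0;
    }
    for (int j = 0; j < nf; ++j) {
      e[j] += (beta[j] * sat[j] * u[j] - (beta[j] + dil_sign * mu_lag) * e[j]) * dt;
      if (e[j] < 0.0) e[j] = 0.0;
      if (e[j] > 1.0) e[j] = 1.0;
    }
    mu_lag = dX / X;
    X += dX * dt;
    if (X < 1e-12) X = 1e-12;
  }
  return out;
}
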