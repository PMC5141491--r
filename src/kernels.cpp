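#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Direct-form-I IIR filter applied down every column of x.
// a0*y[t] = sum_k b[k] x[t-k] - sum_{k>=1} a[k] y[t-k]
// [[Rcpp::export]]
NumericMatrix iir_filter_cpp(NumericVector b, NumericVector a, NumericMatrix x) {
  const int n = x.nrow(), m = x.ncol(), nb = b.size(), na = a.size();
  const double a0 = a[0];
  NumericMatrix y(n, m);
  const double *bp = b.begin(), *ap = a.begin();
  const int warm = std::max(nb, na) - 1;
  for (int c = 0; c < m; ++c) {
    const double *xc = &x(0, c);
    double *yc = &y(0, c);
    int t = 0;
    for (; t < std::min(warm, n); ++t) {         // ramp-up with bounds checks
      double acc = 0.0;
      const int kb = std::min(nb - 1, t);
      for (int k = 0; k <= kb; ++k) acc += bp[k] * xc[t - k];
      const int ka = std::min(na - 1, t);
      for (int k = 1; k <= ka; ++k) acc -= ap[k] * yc[t - k];
      yc[t] = acc / a0;
    }
    for (; t < n; ++t) {                         // steady state, no bounds
      double acc = bp[0] * xc[t];
      for (int k = 1; k < nb; ++k) acc += bp[k] * xc[t - k];
      for (int k = 1; k < na; ++k) acc -= ap[k] * yc[t - k];
      yc[t] = acc / a0;
    }
  }
  return y;
}

// Euler evolution of tree-coupled phase oscillators.
// det_step holds the uncoupled per-sample phase increments (frequency term
// plus phase diffusion), n_channels x (T-1). child/par are 0-based endpoint
// indices per tree edge; wc/wp the degree-normalized pull gains.
// [[Rcpp::export]]
NumericMatrix evolve_phases_cpp(NumericVector theta0, NumericMatrix det_step,
                                IntegerVector child, IntegerVector par,
                                NumericVector wc, NumericVector wp,
                                double lag) {
  const int n = theta0.size();
  const int T = det_step.ncol() + 1;
  const int nE = child.size();
  NumericMatrix theta(n, T);
  std::vector<double> ph(n), step(n);
  for (int i = 0; i < n; ++i) { ph[i] = theta0[i]; theta(i, 0) = ph[i]; }
  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < n; ++i) step[i] = det_step(i, t - 1);
    for (int e = 0; e < nE; ++e) {
      const double s = std::sin(ph[par[e]] - lag - ph[child[e]]);
      step[child[e]] += wc[e] * s;
      step[par[e]]   -= wp[e] * s;
    }
    for (int i = 0; i < n; ++i) { ph[i] += step[i]; theta(i, t) = ph[i]; }
  }
  return theta;
}

// Per-pair |mean over samples of sign(sin(phi_i - phi_j))| for all unordered
// pairs of rows of a channels x samples phase matrix; returns the vector in
// upper-triangle column order.
// [[Rcpp::export]]
NumericVector pli_pairs_cpp(NumericMatrix ph) {
  const int n = ph.nrow(), T = ph.ncol();
  NumericVector out(n * (n - 1) / 2);
  int idx = 0;
  for (int j = 1; j < n; ++j) {
    for (int i = 0; i < j; ++i) {
      double acc = 0.0;
      for (int t = 0; t < T; ++t) {
        const double s = std::sin(ph(i, t) - ph(j, t));
        acc += (s > 0.0) - (s < 0.0);
      }
      out[idx++] = std::fabs(acc / T);
    }
  }
  return out;
}
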