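#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion for one observation sequence.
// logdens: T x N matrix of per-dive state log-densities; Gamma: N x N
// row-stochastic transition matrix; delta: initial distribution.
// Returns the exact log-likelihood; stable for densities spanning
// hundreds of log units because each step is renormalised and the
// per-row maximum of logdens is factored out before exponentiation.
// [[Rcpp::export]]
double forward_loglik_cpp(NumericMatrix logdens, NumericMatrix Gamma,
                          NumericVector delta) {
  const int T = logdens.nrow(), N = logdens.ncol();
  std::vector<double> v(N), w(N);
  double lscale = 0.0;

  double m = logdens(0, 0);
  for (int j = 1; j < N; ++j) m = std::max(m, logdens(0, j));
  if (!R_finite(m)) return R_NegInf;
  double s = 0.0;
  for (int j = 0; j < N; ++j) {
    v[j] = delta[j] * std::exp(logdens(0, j) - m);
    s += v[j];
  }
  if (s <= 0.0) return R_NegInf;
  lscale += m + std::log(s);
  for (int j = 0; j < N; ++j) v[j] /= s;

  for (int t = 1; t < T; ++t) {
    m = logdens(t, 0);
    for (int j = 1; j < N; ++j) m = std::max(m, logdens(t, j));
    if (!R_finite(m)) return R_NegInf;
    s = 0.0;
    for (int j = 0; j < N; ++j) {
      double a = 0.0;
      for (int i = 0; i < N; ++i) a += v[i] * Gamma(i, j);
      w[j] = a * std::exp(logdens(t, j) - m);
      s += w[j];
    }
    if (s <= 0.0) return R_NegInf;
    lscale += m + std::log(s);
    for (int j = 0; j < N; ++j) v[j] = w[j] / s;
  }
  return lscale;
}

static double forward_block(const NumericMatrix& logdens, int off, int T,
                            const double* G, int N, const double* delta) {
  std::vector<double> v(N), w(N);
  double lscale = 0.0, m, s;

  m = logdens(off, 0);
  for (int j = 1; j < N; ++j) m = std::max(m, logdens(off, j));
  if (!R_finite(m)) return R_NegInf;
  s = 0.0;
  for (int j = 0; j < N; ++j) {
    v[j] = delta[j] * std::exp(logdens(off, j) - m);
    s += v[j];
  }
  if (s <= 0.0) return R_NegInf;
  lscale += m + std::log(s);
  for (int j = 0; j < N; ++j) v[j] /= s;

  for (int t = 1; t < T; ++t) {
    const int r = off + t;
    m = logdens(r, 0);
    for (int j = 1; j < N; ++j) m = std::max(m, logdens(r, j));
    if (!R_finite(m)) return R_NegInf;
    s = 0.0;
    for (int j = 0; j < N; ++j) {
      double a = 0.0;
      for (int i = 0; i < N; ++i) a += v[i] * G[i + j * N]; // column-major
      w[j] = a * std::exp(logdens(r, j) - m);
      s += w[j];
    }
    if (s <= 0.0) return R_NegInf;
    lscale += m + std::log(s);
    for (int j = 0; j < N; ++j) v[j] = w[j] / s;
  }
  return lscale;
}

// Total mixture log-likelihood over whale blocks stacked in logdens.
// lens: per-whale sequence lengths; Gammas: N*N*K column-major array;
// deltas: K x N matrix of per-component initial distributions.
// [[Rcpp::export]]
double mixture_loglik_groups_cpp(NumericMatrix logdens, IntegerVector lens,
                                 NumericVector Gammas, int N, int K,
                                 NumericVector omega, NumericMatrix deltas) {
  double total = 0.0;
  int off = 0;
  std::vector<double> lw(K), dk(N);
  for (int wgt = 0; wgt < lens.size(); ++wgt) {
    const int T = lens[wgt];
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < N; ++j) dk[j] = deltas(k, j);
      double ll = forward_block(logdens, off, T, &Gammas[k * N * N], N,
                                dk.data());
      lw[k] = std::log(omega[k]) + ll;
    }
    double m = lw[0];
    for (int k = 1; k < K; ++k) m = std::max(m, lw[k]);
    if (!R_finite(m)) return R_NegInf;
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(lw[k] - m);
    total += m + std::log(s);
    off += T;
  }
  return total;
}
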