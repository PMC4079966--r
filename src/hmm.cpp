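#include <Rcpp.h>
using namespace Rcpp;

// Log-space HMM recursions. logdens is T x K (per-bin emission log
// densities), logpi length K, logtrans K x K (rows = from). All outputs on
// the natural-log scale.

static inline double logsumexp(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// Forward-backward: returns gamma (T x K posterior state probabilities),
// xi summed over time (K x K expected transition counts) and the data
// log-likelihood.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix logdens, NumericVector logpi,
            NumericMatrix logtrans) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix la(T, K), lb(T, K);
  std::vector<double> tmp(K);

  for (int k = 0; k < K; ++k) la(0, k) = logpi[k] + logdens(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) tmp[j] = la(t - 1, j) + logtrans(j, k);
      la(t, k) = logsumexp(tmp) + logdens(t, k);
    }
  }
  for (int k = 0; k < K; ++k) tmp[k] = la(T - 1, k);
  const double loglik = logsumexp(tmp);

  for (int k = 0; k < K; ++k) lb(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k)
        tmp[k] = logtrans(j, k) + logdens(t + 1, k) + lb(t + 1, k);
      lb(t, j) = logsumexp(tmp);
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      gamma(t, k) = std::exp(la(t, k) + lb(t, k) - loglik);

  NumericMatrix xi(K, K);
  for (int t = 0; t + 1 < T; ++t)
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += std::exp(la(t, j) + logtrans(j, k) +
                             logdens(t + 1, k) + lb(t + 1, k) - loglik);

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = loglik);
}

// Viterbi maximum a posteriori path; ties broken toward the lower state
// index (strict > comparison scanning states in order). Returns the
// 1-based path and its log-probability.
// [[Rcpp::export(name = ".viterbi_cpp")]]
List viterbi_cpp(NumericMatrix logdens, NumericVector logpi,
                 NumericMatrix logtrans) {
  const int T = logdens.nrow(), K = logdens.ncol();
  if (T == 0)
    return List::create(_["path"] = IntegerVector(0),
                        _["logprob"] = R_NegInf);
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);

  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logdens(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      int arg = 0;
      double best = delta(t - 1, 0) + logtrans(0, k);
      for (int j = 1; j < K; ++j) {
        double cand = delta(t - 1, j) + logtrans(j, k);
        if (cand > best) { best = cand; arg = j; }
      }
      delta(t, k) = best + logdens(t, k);
      psi(t, k) = arg;
    }
  }

  int last = 0;
  double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); last = k; }

  IntegerVector path(T);
  path[T - 1] = last + 1;
  for (int t = T - 1; t > 0; --t) {
    last = psi(t, last);
    path[t - 1] = last + 1;
  }
  return List::create(_["path"] = path, _["logprob"] = best);
}
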