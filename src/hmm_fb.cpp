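// Log-space forward-backward and Viterbi recursions for a Gaussian-emission
// HMM over concatenated runs. Each run restarts from the initial distribution
// and no transition is counted across a run boundary.
#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static inline double logsumexp_row(const std::vector<double>& x) {
  double m = -DBL_MAX;
  for (double v : x) if (v > m) m = v;
  if (m == -DBL_MAX) return m;
  double s = 0.0;
  for (double v : x) s += std::exp(v - m);
  return m + std::log(s);
}

// logB: T x K log emission densities; logA: K x K log transition matrix;
// logpi: K log initial probabilities; starts: 0-based run start offsets.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix logB, NumericMatrix logA, NumericVector logpi,
            IntegerVector starts) {
  const int T = logB.nrow(), K = logB.ncol(), R = starts.size();
  NumericMatrix la(T, K), lb(T, K), gamma(T, K), xi(K, K);
  std::fill(xi.begin(), xi.end(), 0.0);
  std::vector<double> tmp(K);
  double loglik = 0.0;

  for (int r = 0; r < R; ++r) {
    const int s = starts[r];
    const int e = (r + 1 < R) ? starts[r + 1] - 1 : T - 1;
    // forward
    for (int k = 0; k < K; ++k) la(s, k) = logpi[k] + logB(s, k);
    for (int t = s + 1; t <= e; ++t) {
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < K; ++j) tmp[j] = la(t - 1, j) + logA(j, k);
        la(t, k) = logsumexp_row(tmp) + logB(t, k);
      }
    }
    for (int k = 0; k < K; ++k) tmp[k] = la(e, k);
    const double ll_run = logsumexp_row(tmp);
    loglik += ll_run;
    // backward
    for (int k = 0; k < K; ++k) lb(e, k) = 0.0;
    for (int t = e - 1; t >= s; --t) {
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < K; ++j)
          tmp[j] = logA(k, j) + logB(t + 1, j) + lb(t + 1, j);
        lb(t, k) = logsumexp_row(tmp);
      }
    }
    // posteriors and pairwise expectations
    for (int t = s; t <= e; ++t) {
      double rs = 0.0;
      for (int k = 0; k < K; ++k) {
        gamma(t, k) = std::exp(la(t, k) + lb(t, k) - ll_run);
        rs += gamma(t, k);
      }
      for (int k = 0; k < K; ++k) gamma(t, k) /= rs;
    }
    for (int t = s + 1; t <= e; ++t) {
      for (int i = 0; i < K; ++i)
        for (int j = 0; j < K; ++j)
          xi(i, j) += std::exp(la(t - 1, i) + logA(i, j) + logB(t, j) +
                               lb(t, j) - ll_run);
    }
  }
  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi,
                      _["log_likelihood"] = loglik);
}

// Viterbi decoding; ties broken toward the lowest state index (strict >).
// [[Rcpp::export(name = ".viterbi_cpp")]]
List viterbi_cpp(NumericMatrix logB, NumericMatrix logA, NumericVector logpi,
                 IntegerVector starts) {
  const int T = logB.nrow(), K = logB.ncol(), R = starts.size();
  IntegerVector path(T);
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  double logprob = 0.0;

  for (int r = 0; r < R; ++r) {
    const int s = starts[r];
    const int e = (r + 1 < R) ? starts[r + 1] - 1 : T - 1;
    for (int k = 0; k < K; ++k) delta(s, k) = logpi[k] + logB(s, k);
    for (int t = s + 1; t <= e; ++t) {
      for (int k = 0; k < K; ++k) {
        int arg = 0;
        double best = delta(t - 1, 0) + logA(0, k);
        for (int j = 1; j < K; ++j) {
          const double v = delta(t - 1, j) + logA(j, k);
          if (v > best) { best = v; arg = j; }
        }
        delta(t, k) = best + logB(t, k);
        psi(t, k) = arg;
      }
    }
    int arg = 0;
    for (int k = 1; k < K; ++k) if (delta(e, k) > delta(e, arg)) arg = k;
    logprob += delta(e, arg);
    path[e] = arg;
    for (int t = e - 1; t >= s; --t) path[t] = psi(t + 1, path[t + 1]);
  }
  return List::create(_["path"] = path, _["log_prob"] = logprob);
}
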