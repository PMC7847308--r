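#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// log-space forward-backward for one sequence with Gaussian emissions.
// Returns loglik, posterior state probabilities gamma (T x K) and the
// expected transition counts xi_sum (K x K).
// [[Rcpp::export]]
List fwdbwd_gauss(NumericVector x, NumericVector mu, NumericVector sigma,
                  NumericMatrix logA, NumericVector logPi) {
  const int T = x.size(), K = mu.size();
  NumericMatrix logB(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double z = (x[t] - mu[k]) / sigma[k];
      logB(t, k) = -0.5 * z * z - std::log(sigma[k]) -
                   0.91893853320467274178; // log(sqrt(2*pi))
    }
  NumericMatrix la(T, K), lb(T, K);
  for (int k = 0; k < K; ++k) la(0, k) = logPi[k] + logB(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double acc = R_NegInf;
      for (int j = 0; j < K; ++j)
        acc = logsumexp2(acc, la(t - 1, j) + logA(j, k));
      la(t, k) = acc + logB(t, k);
    }
  double ll = R_NegInf;
  for (int k = 0; k < K; ++k) ll = logsumexp2(ll, la(T - 1, k));

  for (int k = 0; k < K; ++k) lb(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t)
    for (int k = 0; k < K; ++k) {
      double acc = R_NegInf;
      for (int j = 0; j < K; ++j)
        acc = logsumexp2(acc, logA(k, j) + logB(t + 1, j) + lb(t + 1, j));
      lb(t, k) = acc;
    }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      gamma(t, k) = std::exp(la(t, k) + lb(t, k) - ll);

  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t)
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += std::exp(la(t, j) + logA(j, k) + logB(t + 1, k) +
                             lb(t + 1, k) - ll);

  return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                      _["xi"] = xi);
}

// Viterbi decoding, ties broken toward the lower state index.
// Returns 1-based state path.
// [[Rcpp::export]]
IntegerVector viterbi_gauss(NumericVector x, NumericVector mu,
                            NumericVector sigma, NumericMatrix logA,
                            NumericVector logPi) {
  const int T = x.size(), K = mu.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  auto logb = [&](int t, int k) {
    double z = (x[t] - mu[k]) / sigma[k];
    return -0.5 * z * z - std::log(sigma[k]) - 0.91893853320467274178;
  };
  for (int k = 0; k < K; ++k) delta(0, k) = logPi[k] + logb(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }  // strict > keeps lowest index on ties
      }
      delta(t, k) = best + logb(t, k);
      psi(t, k) = arg;
    }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}

// largest t-like mean-difference statistic over all split points of x,
// given a fixed noise sigma; returns (best index, best statistic).
// Split at i means segments [1..i] and [i+1..n] (1-based i).
// [[Rcpp::export]]
List best_split(NumericVector x, double sigma, int min_seg) {
  const int n = x.size();
  double best = -1.0; int arg = -1;
  if (n < 2 * min_seg) return List::create(_["index"] = arg, _["stat"] = best);
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
  for (int i = min_seg; i <= n - min_seg; ++i) {
    double m1 = cs[i] / i;
    double m2 = (cs[n] - cs[i]) / (n - i);
    double stat = std::fabs(m1 - m2) /
                  (sigma * std::sqrt(1.0 / i + 1.0 / (n - i)));
    if (stat > best) { best = stat; arg = i; }
  }
  return List::create(_["index"] = arg, _["stat"] = best);
}
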