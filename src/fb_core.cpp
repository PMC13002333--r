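#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursion on pre-exponentiated emission
// likelihoods b (T x K, each row scaled by its max so values are in (0, 1]).
// Returns posterior state probabilities gamma, expected transition counts
// xi (summed over transitions) and the sum of log scaling constants.
// [[Rcpp::export(name = ".fb_core")]]
List fb_core(NumericMatrix b, NumericMatrix A, NumericVector init) {
  const int T = b.nrow(), K = b.ncol();
  NumericMatrix alpha(T, K), gamma(T, K), xi(K, K);
  NumericVector cs(T);
  std::vector<double> beta(K), beta_next(K), tmp(K);

  double c0 = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = init[k] * b(0, k);
    c0 += alpha(0, k);
  }
  if (c0 <= 0.0) stop("zero likelihood under every state at trial 1");
  cs[0] = c0;
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;

  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int k = 0; k < K; ++k) a += alpha(t - 1, k) * A(k, j);
      a *= b(t, j);
      alpha(t, j) = a;
      ct += a;
    }
    if (ct <= 0.0) stop("numerical underflow: zero likelihood at trial %d",
                        t + 1);
    cs[t] = ct;
    for (int j = 0; j < K; ++j) alpha(t, j) /= ct;
  }

  for (int k = 0; k < K; ++k) {
    beta[k] = 1.0;
    gamma(T - 1, k) = alpha(T - 1, k);
  }
  for (int t = T - 2; t >= 0; --t) {
    const double cinv = 1.0 / cs[t + 1];
    for (int j = 0; j < K; ++j) tmp[j] = b(t + 1, j) * beta[j];
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) {
        const double contrib = alpha(t, k) * A(k, j) * tmp[j] * cinv;
        xi(k, j) += contrib;
        s += A(k, j) * tmp[j];
      }
      beta_next[k] = s * cinv;
    }
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      beta[k] = beta_next[k];
      gamma(t, k) = alpha(t, k) * beta[k];
      g += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  double logc = 0.0;
  for (int t = 0; t < T; ++t) logc += std::log(cs[t]);
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["logc"] = logc);
}
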