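#include <Rcpp.h>
using namespace Rcpp;

// Expectation-maximization for a two-component zero-mean Gaussian mixture.
// Both means are fixed at zero; free parameters are the two standard
// deviations and the mixing weight of component 1.  The log-likelihood is
// nondecreasing across iterations (standard EM guarantee); convergence is
// declared when the per-sample improvement drops below `tol`.
// [[Rcpp::export]]
List cpp_em_fit(NumericVector x, double sigma1, double sigma2, double alpha,
                int max_iter, double tol) {
  const int n = x.size();
  if (n < 2) stop("need at least 2 samples");
  std::vector<double> ll_trace;
  ll_trace.reserve(64);
  const double log2pi_half = 0.5 * std::log(2.0 * M_PI);
  double ll_prev = -std::numeric_limits<double>::infinity();
  int it = 0;
  bool converged = false;

  for (it = 0; it < max_iter; ++it) {
    const double inv1 = 1.0 / sigma1, inv2 = 1.0 / sigma2;
    const double lw1 = std::log(alpha) - std::log(sigma1) - log2pi_half;
    const double lw2 = std::log1p(-alpha) - std::log(sigma2) - log2pi_half;
    double ll = 0.0, sum_r = 0.0, s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xi = x[i];
      const double l1 = lw1 - 0.5 * xi * xi * inv1 * inv1;
      const double l2 = lw2 - 0.5 * xi * xi * inv2 * inv2;
      // log-sum-exp for numerical safety in the far tails
      const double m = l1 > l2 ? l1 : l2;
      const double t = std::exp(l1 - m) + std::exp(l2 - m);
      ll += m + std::log(t);
      const double r = std::exp(l1 - m) / t;
      sum_r += r;
      s1 += r * xi * xi;
      s2 += (1.0 - r) * xi * xi;
    }
    ll_trace.push_back(ll);
    // M-step (guard against a component collapsing to zero weight)
    double a_new = sum_r / n;
    a_new = std::min(std::max(a_new, 1e-12), 1.0 - 1e-12);
    if (sum_r > 0) sigma1 = std::sqrt(s1 / sum_r);
    if (n - sum_r > 0) sigma2 = std::sqrt(s2 / (n - sum_r));
    sigma1 = std::max(sigma1, 1e-9);
    sigma2 = std::max(sigma2, 1e-9);
    alpha = a_new;
    if (it > 0 && (ll - ll_prev) < tol * n) { converged = true; ++it; break; }
    ll_prev = ll;
  }

  return List::create(
    _["sigma1"] = sigma1, _["sigma2"] = sigma2, _["alpha"] = alpha,
    _["loglik"] = NumericVector(ll_trace.begin(), ll_trace.end()),
    _["iterations"] = it, _["converged"] = converged);
}
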