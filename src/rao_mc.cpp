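#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double TWO_PI = 6.2831853071795864769252867665590;

// U = 0.5 * sum_i |T_i - 2*pi/n| for a sorted sample on [0, 2*pi), where the
// T_i are the n neighbour arcs including the wrap-around arc across 0.
static double rao_u_from_sorted(const std::vector<double>& x) {
  const int n = static_cast<int>(x.size());
  const double expected = TWO_PI / n;
  double u = 0.0;
  for (int i = 0; i + 1 < n; ++i) u += std::fabs(x[i + 1] - x[i] - expected);
  u += std::fabs(TWO_PI - x[n - 1] + x[0] - expected);
  return 0.5 * u;
}

// [[Rcpp::export]]
double cpp_rao_u(NumericVector phi) {
  std::vector<double> x(phi.begin(), phi.end());
  std::sort(x.begin(), x.end());
  return rao_u_from_sorted(x);
}

static inline double wrap_two_pi(double x) {
  x -= TWO_PI * std::floor(x / TWO_PI);
  if (x >= TWO_PI) x -= TWO_PI;  // guard against rounding up to TWO_PI
  if (x < 0.0) x = 0.0;
  return x;
}

// One von Mises(mu, kappa) draw by the Best & Fisher rejection method.
// Uses R's RNG stream so set.seed() in R governs reproducibility.
static double rvm_one(double mu, double kappa) {
  if (kappa <= 0.0) return unif_rand() * TWO_PI;
  const double a = 1.0 + std::sqrt(1.0 + 4.0 * kappa * kappa);
  const double b = (a - std::sqrt(2.0 * a)) / (2.0 * kappa);
  const double r = (1.0 + b * b) / (2.0 * b);
  double f;
  for (;;) {
    const double z = std::cos(M_PI * unif_rand());
    f = (1.0 + r * z) / (r + z);
    const double c = kappa * (r - f);
    const double u2 = unif_rand();
    if (c * (2.0 - c) - u2 > 0.0) break;
    if (std::log(c / u2) + 1.0 - c >= 0.0) break;
  }
  const double theta = (unif_rand() > 0.5 ? 1.0 : -1.0) * std::acos(f) + mu;
  return wrap_two_pi(theta);
}

// [[Rcpp::export]]
NumericVector cpp_rvonmises(int n, double mu, double kappa) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rvm_one(mu, kappa);
  return out;
}

// Monte Carlo null distribution of U: nr resamples of size n from the
// circular uniform, optionally rounded to n_bins equal divisions
// (n_bins <= 0 means continuous) and optionally jittered with
// von Mises(0, kappa) perturbations (the rounded-data null).
// Returned U values are in radians.
// [[Rcpp::export]]
NumericVector cpp_null_u(int n, int nr, int n_bins, double kappa,
                         bool perturb) {
  NumericVector out(nr);
  std::vector<double> x(n);
  const double width = n_bins > 0 ? TWO_PI / n_bins : 0.0;
  for (int j = 0; j < nr; ++j) {
    for (int i = 0; i < n; ++i) {
      double v = unif_rand() * TWO_PI;
      if (n_bins > 0) {
        v = std::round(v / width) * width;
        if (v >= TWO_PI) v -= TWO_PI;
      }
      if (perturb) v = wrap_two_pi(v + rvm_one(0.0, kappa));
      x[i] = v;
    }
    std::sort(x.begin(), x.end());
    out[j] = rao_u_from_sorted(x);
  }
  return out;
}
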