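#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Core AR(1)+GJR-GARCH(1,1)-t log-likelihood: the variance recursion and
// the standardized-t density in one pass. Admissibility is checked by the
// R wrapper; sigma^2_1 starts at the sample variance of the residuals.
// [[Rcpp::export(name = ".garch_loglik_cpp")]]
double garch_loglik_cpp(NumericVector params, NumericVector x) {
  const double c0 = params[0], c1 = params[1], omega = params[2],
               alpha = params[3], beta = params[4], gamma = params[5],
               dof = params[6];
  const int n = x.size();
  const int m = n - 1;
  if (m < 2) return R_NegInf;

  std::vector<double> a(m);
  double mean_a = 0.0;
  for (int i = 0; i < m; ++i) {
    a[i] = x[i + 1] - c0 - c1 * x[i];
    mean_a += a[i];
  }
  mean_a /= m;
  double var_a = 0.0;
  for (int i = 0; i < m; ++i) var_a += (a[i] - mean_a) * (a[i] - mean_a);
  var_a /= (m - 1);
  if (var_a <= 0) return R_NegInf;

  const double s2scale = dof / (dof - 2.0);  // (z*s)^2 multiplier
  const double lconst = R::lgammafn((dof + 1.0) / 2.0) -
                        R::lgammafn(dof / 2.0) -
                        0.5 * std::log(M_PI * dof) +
                        0.5 * std::log(s2scale);
  double ll = 0.0;
  double s2 = var_a;
  for (int i = 0; i < m; ++i) {
    if (i > 0)
      s2 = omega + (alpha + (a[i - 1] < 0 ? gamma : 0.0)) * a[i - 1] * a[i - 1]
           + beta * s2;
    if (s2 <= 0 || !std::isfinite(s2)) return R_NegInf;
    double z2 = a[i] * a[i] / s2;
    ll += lconst - 0.5 * (dof + 1.0) * std::log1p(z2 * s2scale / dof)
          - 0.5 * std::log(s2);
  }
  return ll;
}
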