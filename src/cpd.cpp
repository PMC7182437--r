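#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// E-step of coherent point drift: Gaussian mixture posteriors between
// target X (N x 3) and moved source T (M x 3) with isotropic variance
// sigma2 and uniform-outlier weight w. Returns the sufficient statistics
// P1 (M), Pt1 (N), PX (M x 3), Np = sum(P) and the mixture log-likelihood.
// [[Rcpp::export]]
List cpd_estep(NumericMatrix X, NumericMatrix T, double sigma2, double w) {
  const int N = X.nrow(), M = T.nrow();
  const double c = std::pow(2.0 * M_PI * sigma2, 1.5) * (w / (1.0 - w)) *
    ((double)M / (double)N);
  NumericVector P1(M), Pt1(N);
  NumericMatrix PX(M, 3);
  double ll = 0.0, Np = 0.0;
  std::vector<double> pmn(M);
  const double inv2s = 1.0 / (2.0 * sigma2);
  for (int n = 0; n < N; ++n) {
    double xn0 = X(n, 0), xn1 = X(n, 1), xn2 = X(n, 2);
    double denom = c;
    for (int m = 0; m < M; ++m) {
      double d0 = xn0 - T(m, 0), d1 = xn1 - T(m, 1), d2 = xn2 - T(m, 2);
      double e = std::exp(-(d0*d0 + d1*d1 + d2*d2) * inv2s);
      pmn[m] = e;
      denom += e;
    }
    if (denom <= 0.0 || !std::isfinite(denom)) denom = 1e-300;
    ll += std::log(denom) - std::log((double)M)
      - 1.5 * std::log(2.0 * M_PI * sigma2) + std::log(1.0 - w);
    double post_sum = 0.0;
    for (int m = 0; m < M; ++m) {
      double p = pmn[m] / denom;
      if (p > 0.0) {
        P1[m] += p;
        PX(m, 0) += p * xn0;
        PX(m, 1) += p * xn1;
        PX(m, 2) += p * xn2;
        post_sum += p;
      }
    }
    Pt1[n] = post_sum;
    Np += post_sum;
  }
  return List::create(_["P1"] = P1, _["Pt1"] = Pt1, _["PX"] = PX,
                      _["Np"] = Np, _["loglik"] = ll);
}
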