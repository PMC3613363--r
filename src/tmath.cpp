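// Hot numeric kernel for the t-logistic link: per-margin Newton solve
// of the two-class normalizer and the loss / loss-derivative pair.
// Only used for t in (1, 2); the t = 1 logistic limit has closed forms
// handled in R.

#include <Rcpp.h>
using namespace Rcpp;

// exp_t for arguments kept in the valid region (x <= 0 when t > 1)
static inline double exp_tu(double x, double t) {
  return std::exp(std::log1p((1.0 - t) * x) / (1.0 - t));
}

// Solve exp_t(u/2 - g) + exp_t(-u/2 - g) = 1 for g.  The residual is
// convex and decreasing in g, so Newton from the lower bound |u|/2
// converges monotonically; iteration stops at the tolerance or when no
// representable improvement remains, with a bisection safeguard.
static double solve_g(double u, double t, double tol) {
  const double au2 = std::fabs(u) / 2.0;
  const double omt = 1.0 - t;   // negative
  // first-order start: g ~ |u|/2 + exp_t(-|u|) (exact as |u| grows)
  double g = au2 + exp_tu(-2.0 * au2, t);
  for (int it = 0; it < 200; ++it) {
    const double La = std::log1p(omt * (u / 2.0 - g));
    const double Lb = std::log1p(omt * (-u / 2.0 - g));
    const double p = std::exp(La / omt);
    const double q = std::exp(Lb / omt);
    const double h = p + q - 1.0;
    if (std::fabs(h) < tol) return g;
    const double hp = std::exp(t * La / omt) + std::exp(t * Lb / omt);
    double gn = g + h / hp;
    if (gn < au2) gn = au2;
    if (gn == g) return g;  // ulp-limited: converged to machine precision
    g = gn;
  }
  double lo = au2, width = 1.0, hi = au2 + width;
  while (exp_tu(u / 2.0 - hi, t) + exp_tu(-u / 2.0 - hi, t) - 1.0 > 0.0) {
    width *= 2.0;
    hi = lo + width;
    if (width > 1e12) break;
  }
  for (int it = 0; it < 200; ++it) {
    const double mid = 0.5 * (lo + hi);
    const double r = exp_tu(u / 2.0 - mid, t) + exp_tu(-u / 2.0 - mid, t) - 1.0;
    if (std::fabs(r) < tol) return mid;
    if (r > 0.0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
NumericVector cpp_t_normalizer(NumericVector u, double t, double tol) {
  const int n = u.size();
  NumericVector g(n);
  for (int i = 0; i < n; ++i) g[i] = solve_g(u[i], t, tol);
  return g;
}

// [[Rcpp::export]]
List cpp_t_loss_grad(NumericVector u, double t, double tol) {
  const int n = u.size();
  NumericVector loss(n), dloss(n);
  for (int i = 0; i < n; ++i) {
    const double g = solve_g(u[i], t, tol);
    const double a = u[i] / 2.0 - g;
    const double p = exp_tu(a, t);
    const double q = exp_tu(-u[i] / 2.0 - g, t);
    loss[i] = -std::log1p((1.0 - t) * a) / (1.0 - t);
    const double pt = std::pow(p, t), qt = std::pow(q, t);
    dloss[i] = -(pt / p) * qt / (pt + qt);
  }
  return List::create(_["loss"] = loss, _["dloss"] = dloss);
}
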