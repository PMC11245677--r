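// Fixed-step RK4 method-of-steps integrator for the two-variable
// delayed-autorepression (Lewis) oscillator:
//
//   dp/dt = a m(t - Tp) - b p(t)
//   dm/dt = k / (1 + (p(t - Tm)/pcrit)^n) - c m(t)
//
// Delayed values come from the stored solution via cubic Hermite
// interpolation on the uniform grid (dense output). Constant pre-history
// m(t) = m0, p(t) = p0 for t <= 0. Each delay must be zero (the term is
// then evaluated at the current stage state) or at least one step long;
// the R wrapper enforces the stricter step <= delay/10.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Grid {
  std::vector<double> m, p, dm, dp;
  double h, m0, p0;
  int filled; // highest node index with stored values

  double interp(const std::vector<double>& y, const std::vector<double>& dy,
                double hist, double t) const {
    if (t <= 0.0) return hist;
    double u = t / h;
    int i = static_cast<int>(u);
    if (i >= filled) i = filled - 1;
    double th = u - i;
    if (th < 1e-12) return y[i];
    double t2 = th * th, t3 = t2 * th;
    return (2 * t3 - 3 * t2 + 1) * y[i] + (t3 - 2 * t2 + th) * h * dy[i] +
           (-2 * t3 + 3 * t2) * y[i + 1] + (t3 - t2) * h * dy[i + 1];
  }
  double m_at(double t) const { return interp(m, dm, m0, t); }
  double p_at(double t) const { return interp(p, dp, p0, t); }
};

struct Rates {
  double a, b, c, k, pcrit, n;
  bool n_is_2;

  double hill(double pd) const {
    if (pd < 0.0) pd = 0.0; // interpolation can undershoot zero marginally
    double x = pd / pcrit;
    double xn = n_is_2 ? x * x : std::pow(x, n);
    return k / (1.0 + xn);
  }
};

} // namespace

// [[Rcpp::export]]
List dde_lewis_rk4(double a, double b, double c, double k, double pcrit,
                   double n, double Tm, double Tp, double t_end, double h,
                   double m0, double p0) {
  const int N = static_cast<int>(std::llround(t_end / h));
  if (N < 1) stop("t_end must allow at least one step");

  Grid g;
  g.h = h;
  g.m0 = m0;
  g.p0 = p0;
  g.m.assign(N + 1, 0.0);
  g.p.assign(N + 1, 0.0);
  g.dm.assign(N + 1, 0.0);
  g.dp.assign(N + 1, 0.0);
  g.filled = 0;

  Rates r{a, b, c, k, pcrit, n, std::fabs(n - 2.0) < 1e-12};

  const bool zero_Tm = (Tm == 0.0), zero_Tp = (Tp == 0.0);

  // stage derivative at time ts with stage state (ms, ps)
  auto deriv = [&](double ts, double ms, double ps, double& fm, double& fp) {
    double pd = zero_Tm ? ps : g.p_at(ts - Tm);
    double md = zero_Tp ? ms : g.m_at(ts - Tp);
    fm = r.hill(pd) - c * ms;
    fp = a * md - b * ps;
  };

  g.m[0] = m0;
  g.p[0] = p0;
  deriv(0.0, m0, p0, g.dm[0], g.dp[0]);

  double k1m, k1p, k2m, k2p, k3m, k3p, k4m, k4p;
  for (int i = 0; i < N; ++i) {
    double t = i * h;
    double m = g.m[i], p = g.p[i];
    deriv(t, m, p, k1m, k1p);
    deriv(t + 0.5 * h, m + 0.5 * h * k1m, p + 0.5 * h * k1p, k2m, k2p);
    deriv(t + 0.5 * h, m + 0.5 * h * k2m, p + 0.5 * h * k2p, k3m, k3p);
    deriv(t + h, m + h * k3m, p + h * k3p, k4m, k4p);
    double mn = m + h / 6.0 * (k1m + 2 * k2m + 2 * k3m + k4m);
    double pn = p + h / 6.0 * (k1p + 2 * k2p + 2 * k3p + k4p);
    if (!std::isfinite(mn) || !std::isfinite(pn))
      stop("integration produced a non-finite state at t = %f min", t + h);
    g.m[i + 1] = mn;
    g.p[i + 1] = pn;
    g.filled = i + 1;
    deriv(t + h, mn, pn, g.dm[i + 1], g.dp[i + 1]);
  }

  return List::create(_["mrna"] = NumericVector(g.m.begin(), g.m.end()),
                      _["protein"] = NumericVector(g.p.begin(), g.p.end()));
}
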