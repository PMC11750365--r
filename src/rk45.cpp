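#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-species Lotka-Volterra competition with a constant herbivore term:
//   dN1/dt = r1 N1 (1 - a11 N1 - a12 N2 - b1 Nh)
//   dN2/dt = r2 N2 (1 - a22 N2 - a21 N1 - b2 Nh)
// Integrated with the Dormand-Prince 5(4) embedded pair, adaptive steps.
// Densities below `clamp` are set to exactly 0 (extinction is absorbing).

static inline void rhs(const double *p, const double *y, double *f) {
  f[0] = p[0] * y[0] * (1.0 - p[2] * y[0] - p[3] * y[1] - p[6] * p[8]);
  f[1] = p[1] * y[1] * (1.0 - p[5] * y[1] - p[4] * y[0] - p[7] * p[8]);
}

// Dormand-Prince tableau
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// 4th-order embedded weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
                    e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

// Integrate from t0 to the last entry of `times`, recording the state at each
// requested time (steps never overshoot a requested time, so no interpolation
// is needed). `times` must be strictly increasing and > t0.
// [[Rcpp::export]]
NumericMatrix rk45_lv2(NumericVector y0, double t0, NumericVector times,
                       NumericVector pars, double rtol, double atol,
                       double clamp) {
  if (y0.size() != 2) stop("y0 must have length 2");
  if (pars.size() != 9) stop("pars must have length 9");
  const double *p = pars.begin();
  int nout = times.size();
  NumericMatrix out(nout, 3);

  double t = t0;
  double y[2] = {y0[0], y0[1]};
  if (y[0] < clamp) y[0] = 0.0;
  if (y[1] < clamp) y[1] = 0.0;

  double tend = times[nout - 1];
  double hmax = tend - t0;
  double h = hmax / 100.0;
  if (h <= 0) stop("times must lie after t0");
  double hmin = 1e-12 * (tend - t0 > 1.0 ? tend - t0 : 1.0);

  double k1[2], k2[2], k3[2], k4[2], k5[2], k6[2], k7[2], yt[2], y5[2];
  rhs(p, y, k1);
  int iout = 0;
  long nstep = 0;

  while (iout < nout) {
    double tnext = times[iout];
    if (t >= tnext - 1e-14 * (std::fabs(tnext) + 1.0)) {
      out(iout, 0) = tnext;
      out(iout, 1) = y[0];
      out(iout, 2) = y[1];
      ++iout;
      continue;
    }
    bool hit = false;
    if (t + h >= tnext) { h = tnext - t; hit = true; }

    for (int i = 0; i < 2; ++i) yt[i] = y[i] + h * a21 * k1[i];
    rhs(p, yt, k2);
    for (int i = 0; i < 2; ++i) yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(p, yt, k3);
    for (int i = 0; i < 2; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(p, yt, k4);
    for (int i = 0; i < 2; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    rhs(p, yt, k5);
    for (int i = 0; i < 2; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    rhs(p, yt, k6);
    for (int i = 0; i < 2; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                          b6 * k6[i]);
    rhs(p, y5, k7);

    // error estimate: 5th order minus embedded 4th order
    double errnorm = 0.0;
    for (int i = 0; i < 2; ++i) {
      double y4 = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                              e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double e = (y5[i] - y4) / sc;
      errnorm += e * e;
    }
    errnorm = std::sqrt(errnorm / 2.0);

    if (errnorm <= 1.0) {  // accept
      t += h;
      for (int i = 0; i < 2; ++i) {
        y[i] = y5[i];
        if (y[i] < clamp) y[i] = 0.0;
        k1[i] = k7[i];  // FSAL
      }
      if (y[0] == 0.0 || y[1] == 0.0) rhs(p, y, k1);
      if (hit && t >= tnext - 1e-14 * (std::fabs(tnext) + 1.0)) {
        out(iout, 0) = tnext;
        out(iout, 1) = y[0];
        out(iout, 2) = y[1];
        ++iout;
      }
    }
    double fac = errnorm > 0.0 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
    if (h > hmax) h = hmax;
    if (h < hmin) {
      if (!R_finite(y[0]) || !R_finite(y[1]) || errnorm > 1.0)
        stop("integrator step underflow at t = %g", t);
      h = hmin;
    }
    if (++nstep > 50000000L) stop("integrator exceeded step budget at t = %g", t);
  }
  return out;
}
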