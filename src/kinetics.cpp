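#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rate functional forms. Integer codes: 0 constant, 1 sigmoid, 2 impulse.
// Parameter order matches the R side:
//   constant: h0
//   sigmoid:  h0, h1, t1, beta
//   impulse:  h0, h1, h2, t1, t2, beta
struct RateSpec {
  int form;
  double p[6];
};

static inline double sigf(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline double rate_at(const RateSpec &r, double t) {
  switch (r.form) {
  case 0:
    return r.p[0];
  case 1:
    return r.p[0] + (r.p[1] - r.p[0]) * sigf(r.p[3] * (t - r.p[2]));
  default: {
    double a = r.p[0] + (r.p[1] - r.p[0]) * sigf(r.p[5] * (t - r.p[3]));
    double b = r.p[2] + (r.p[1] - r.p[2]) * sigf(-r.p[5] * (t - r.p[4]));
    return a * b / r.p[1];
  }
  }
}

static inline void deriv(const RateSpec *ks, double t, const double *y,
                         double *dy) {
  double k1 = rate_at(ks[0], t);
  double k2 = rate_at(ks[1], t);
  double k3 = rate_at(ks[2], t);
  dy[0] = k1 - k2 * y[0];
  dy[1] = k2 * y[0] - k3 * y[1];
}

// One Cash-Karp RK45 step from (t, y) with step h; yout gets the 5th-order
// solution, yerr the embedded 4th/5th-order error estimate.
static void rkck_step(const RateSpec *ks, double t, const double *y, double h,
                      double *yout, double *yerr) {
  static const double a2 = 0.2, a3 = 0.3, a4 = 0.6, a5 = 1.0, a6 = 0.875;
  static const double b21 = 0.2;
  static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  static const double b41 = 0.3, b42 = -0.9, b43 = 1.2;
  static const double b51 = -11.0 / 54.0, b52 = 2.5, b53 = -70.0 / 27.0,
                      b54 = 35.0 / 27.0;
  static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                      b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                      b65 = 253.0 / 4096.0;
  static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                      c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
  static const double dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
                      dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
                      dc6 = c6 - 0.25;

  double k1[2], k2[2], k3[2], k4[2], k5[2], k6[2], ytmp[2];
  deriv(ks, t, y, k1);
  for (int i = 0; i < 2; ++i) ytmp[i] = y[i] + h * b21 * k1[i];
  deriv(ks, t + a2 * h, ytmp, k2);
  for (int i = 0; i < 2; ++i) ytmp[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
  deriv(ks, t + a3 * h, ytmp, k3);
  for (int i = 0; i < 2; ++i)
    ytmp[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
  deriv(ks, t + a4 * h, ytmp, k4);
  for (int i = 0; i < 2; ++i)
    ytmp[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
  deriv(ks, t + a5 * h, ytmp, k5);
  for (int i = 0; i < 2; ++i)
    ytmp[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                          b64 * k4[i] + b65 * k5[i]);
  deriv(ks, t + a6 * h, ytmp, k6);
  for (int i = 0; i < 2; ++i) {
    yout[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
    yerr[i] = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] + dc5 * k5[i] +
                   dc6 * k6[i]);
  }
}

// Adaptive integration of y from t to t_end. Returns false on step-size
// underflow or non-finite state; t is updated to the last accepted time.
static bool integrate_to(const RateSpec *ks, double &t, double *y,
                         double t_end, double rtol, double atol) {
  const double tiny = 1e-12;
  double h = t_end - t;
  if (h <= 0.0) return true;
  // conservative first step: bounded by the fastest first-order timescale
  double kmax = std::max(rate_at(ks[1], t), rate_at(ks[2], t));
  if (kmax > 0.0 && std::isfinite(kmax)) h = std::min(h, 0.1 / kmax);
  long max_steps = 1000000;
  for (long it = 0; it < max_steps; ++it) {
    if (t >= t_end - tiny * (std::fabs(t_end) + 1.0)) return true;
    if (t + h > t_end) h = t_end - t;
    double yout[2], yerr[2];
    rkck_step(ks, t, y, h, yout, yerr);
    double errmax = 0.0;
    for (int i = 0; i < 2; ++i) {
      double sk = atol + rtol * std::max(std::fabs(y[i]), std::fabs(yout[i]));
      errmax = std::max(errmax, std::fabs(yerr[i]) / sk);
    }
    if (!std::isfinite(errmax)) return false;
    if (errmax <= 1.0) {
      t += h;
      y[0] = yout[0];
      y[1] = yout[1];
      double grow =
          (errmax > 1e-10) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      h *= std::min(5.0, grow);
      if (!std::isfinite(y[0]) || !std::isfinite(y[1])) return false;
    } else {
      h *= std::max(0.1, 0.9 * std::pow(errmax, -0.25));
      if (std::fabs(h) < 1e-13 * (std::fabs(t) + 1.0)) return false;
    }
  }
  return false;
}

static void fill_specs(const IntegerVector &forms, const List &params,
                       RateSpec *ks) {
  for (int r = 0; r < 3; ++r) {
    ks[r].form = forms[r];
    NumericVector p = params[r];
    for (int j = 0; j < p.size() && j < 6; ++j) ks[r].p[j] = p[j];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_solve_kinetics(IntegerVector forms, List params,
                                 NumericVector times, double P0, double M0,
                                 double rtol, double atol) {
  RateSpec ks[3];
  fill_specs(forms, params, ks);
  int n = times.size();
  NumericMatrix out(n, 2);
  double y[2] = {P0, M0};
  double t = times[0];
  out(0, 0) = y[0];
  out(0, 1) = y[1];
  for (int i = 1; i < n; ++i) {
    if (!integrate_to(ks, t, y, times[i], rtol, atol)) {
      stop("ODE integration failed; last accepted time %f", t);
    }
    out(i, 0) = y[0];
    out(i, 1) = y[1];
  }
  return out;
}

// Weighted least-squares objective for fitting. obs and w are n_times x
// n_species matrices with columns (premature, mature[, synthesis]); w holds
// the inverse variances of the replicate means. Initial conditions are the
// steady state implied by the rate values at times[0]. Returns +Inf when the
// integration fails or the state degenerates, so optimizers back off.
// [[Rcpp::export]]
double cpp_chi2(IntegerVector forms, List params, NumericVector times,
                NumericMatrix obs, NumericMatrix w, bool has_synthesis,
                double rtol, double atol) {
  RateSpec ks[3];
  fill_specs(forms, params, ks);
  int n = times.size();
  double t0 = times[0];
  double k1v = rate_at(ks[0], t0);
  double k2v = rate_at(ks[1], t0);
  double k3v = rate_at(ks[2], t0);
  if (!(k1v > 0.0) || !(k2v > 0.0) || !(k3v > 0.0)) return R_PosInf;
  double y[2] = {k1v / k2v, k1v / k3v};
  if (!std::isfinite(y[0]) || !std::isfinite(y[1])) return R_PosInf;
  double chi2 = 0.0;
  double t = t0;
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      if (!integrate_to(ks, t, y, times[i], rtol, atol)) return R_PosInf;
    }
    double rp = y[0] - obs(i, 0);
    double rm = y[1] - obs(i, 1);
    chi2 += w(i, 0) * rp * rp + w(i, 1) * rm * rm;
    if (has_synthesis) {
      double rs = rate_at(ks[0], times[i]) - obs(i, 2);
      chi2 += w(i, 2) * rs * rs;
    }
  }
  if (!std::isfinite(chi2)) return R_PosInf;
  return chi2;
}
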