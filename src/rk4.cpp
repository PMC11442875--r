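// Adaptive step-doubling RK4 core for the tumor/T-cell population model.
//
// State layout: s[0..M-1] = cancer subpopulations y_i (CI units),
//               s[M] = active T cells x_A, s[M+1] = exhausted T cells x_E.
// Parameter vector ("theta") layout, packed by as_theta() on the R side:
//   [M, r(M), d(M), a(M), K, h(M), l(M), b_A, b_E, r_A, d_E, C]
//
// The integrator rejects any step whose accepted state would leave the
// nonnegative orthant (halving the step instead), floors components with
// magnitude < 1e-12 to zero, and uses local extrapolation of the
// two-half-steps solution (error scaled by 1/15).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int M;
  const double *r, *d, *a, *h, *l;
  double K, bA, bE, rA, dE, C;
};

Model unpack(const double* th) {
  Model m;
  m.M = static_cast<int>(th[0]);
  const double* p = th + 1;
  m.r = p; p += m.M;
  m.d = p; p += m.M;
  m.a = p; p += m.M;
  m.K = *p++;
  m.h = p; p += m.M;
  m.l = p; p += m.M;
  m.bA = *p++;
  m.bE = *p++;
  m.rA = *p++;
  m.dE = *p++;
  m.C = *p++;
  return m;
}

inline void rhs(const Model& m, const double* s, double* ds) {
  double S = 0.0, L = 0.0;
  for (int i = 0; i < m.M; ++i) {
    S += m.a[i] * s[i];
    L += m.l[i] * s[i];
  }
  const double xA = s[m.M], xE = s[m.M + 1];
  const double crowd = 1.0 - S / m.K;
  for (int i = 0; i < m.M; ++i)
    ds[i] = m.r[i] * s[i] * crowd - m.d[i] * s[i] - m.h[i] * s[i] * xA;
  ds[m.M]     = m.rA * xA * (1.0 - (m.bA * xA + m.bE * xE) / m.C) - xA * L;
  ds[m.M + 1] = xA * L - m.dE * xE;
}

// One classic RK4 step of size hstep from y into out (k1 may be precomputed).
inline void rk4_step(const Model& m, const double* y, double hstep, const double* k1,
                     double* out, double* k2, double* k3, double* k4, double* tmp, int n) {
  for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * hstep * k1[i];
  rhs(m, tmp, k2);
  for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * hstep * k2[i];
  rhs(m, tmp, k3);
  for (int i = 0; i < n; ++i) tmp[i] = y[i] + hstep * k3[i];
  rhs(m, tmp, k4);
  for (int i = 0; i < n; ++i)
    out[i] = y[i] + hstep / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

struct Settings {
  double rtol, atol, h0, hmin, hmax, safety;
  int max_steps;
};

const double FLOOR_EPS = 1e-12;

// Cubic Hermite evaluation of scalar value on [ta, ta+h].
inline double hermite(double theta, double hstep, double ya, double fa,
                      double yb, double fb) {
  const double t2 = theta * theta, t3 = t2 * theta;
  return (2.0 * t3 - 3.0 * t2 + 1.0) * ya + (t3 - 2.0 * t2 + theta) * hstep * fa +
         (-2.0 * t3 + 3.0 * t2) * yb + (t3 - t2) * hstep * fb;
}

struct Recorder {
  std::vector<double> t;
  std::vector<double> y;   // row-major, n per row
  std::vector<double> dy;  // row-major, n per row
  void push(double tt, const double* yy, const double* ff, int n) {
    t.push_back(tt);
    y.insert(y.end(), yy, yy + n);
    dy.insert(dy.end(), ff, ff + n);
  }
};

// Integrate from t0 to t1.  Optionally records accepted steps, and/or emits the
// observable CI (sum of y_i) at sorted output times tout via Hermite dense
// output.  Returns true on success; on failure *t_fail holds the failure time.
bool integrate_core(const Model& m, std::vector<double>& y, double t0, double t1,
                    const Settings& st, Recorder* rec,
                    const double* tout, int nout, double* ci_out, int& iout,
                    double* t_fail) {
  const int n = m.M + 2;
  std::vector<double> f(n), k2(n), k3(n), k4(n), tmp(n);
  std::vector<double> y_full(n), y_half(n), y_mid(n), fmid(n), y_new(n), f_new(n);

  double t = t0;
  double hstep = std::min(st.h0, std::max(t1 - t0, st.hmin));

  rhs(m, y.data(), f.data());
  if (rec) rec->push(t, y.data(), f.data(), n);
  // outputs at or before t0 (grid usually starts exactly at t0)
  while (iout < nout && tout[iout] <= t + 1e-12) {
    double s = 0.0;
    for (int i = 0; i < m.M; ++i) s += y[i];
    ci_out[iout++] = s;
  }

  int steps = 0;
  while (t < t1 - 1e-12) {
    if (++steps > st.max_steps) { *t_fail = t; return false; }
    bool clamped = false;
    if (hstep > t1 - t) { hstep = t1 - t; clamped = true; }

    // one full step
    rk4_step(m, y.data(), hstep, f.data(), y_full.data(), k2.data(), k3.data(),
             k4.data(), tmp.data(), n);
    // two half steps
    const double hh = 0.5 * hstep;
    rk4_step(m, y.data(), hh, f.data(), y_mid.data(), k2.data(), k3.data(),
             k4.data(), tmp.data(), n);
    rhs(m, y_mid.data(), fmid.data());
    rk4_step(m, y_mid.data(), hh, fmid.data(), y_half.data(), k2.data(), k3.data(),
             k4.data(), tmp.data(), n);

    // error estimate (step doubling, order 4: scale difference by 1/15)
    double errnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      const double sc = st.atol + st.rtol * std::max(std::fabs(y[i]), std::fabs(y_half[i]));
      const double e = std::fabs(y_half[i] - y_full[i]) / (15.0 * sc);
      if (e > errnorm) errnorm = e;
    }

    bool neg = false;
    if (errnorm <= 1.0) {
      for (int i = 0; i < n; ++i) {
        y_new[i] = y_half[i] + (y_half[i] - y_full[i]) / 15.0;  // local extrapolation
        if (std::fabs(y_new[i]) < FLOOR_EPS) y_new[i] = 0.0;
        if (y_new[i] < 0.0) neg = true;
      }
    }

    if (errnorm > 1.0 || neg) {
      // reject: shrink (halve on negativity, error-scaled otherwise)
      double fac = neg ? 0.5 : std::max(0.1, st.safety * std::pow(errnorm, -0.25));
      hstep *= fac;
      if (hstep < st.hmin) { *t_fail = t; return false; }
      continue;
    }

    // accept
    t = clamped ? t1 : t + hstep;
    y.swap(y_new);
    rhs(m, y.data(), f_new.data());

    // dense output over (t_prev, t]
    const double t_prev = clamped ? t1 - hstep : t - hstep;
    while (iout < nout && tout[iout] <= t + 1e-12) {
      const double theta = (tout[iout] - t_prev) / hstep;
      // Hermite is linear, so interpolate the summed observable directly.
      // After the swap, y_new holds the *previous* state; f is still its rhs.
      double s_old = 0.0, s_new = 0.0, df_old = 0.0, df_new = 0.0;
      for (int i = 0; i < m.M; ++i) {
        s_old += y_new[i];
        s_new += y[i];
        df_old += f[i];
        df_new += f_new[i];
      }
      ci_out[iout++] = hermite(theta, hstep, s_old, df_old, s_new, df_new);
    }

    f.swap(f_new);
    if (rec) rec->push(t, y.data(), f.data(), n);

    // step-size growth for next step
    double fac = (errnorm > 0.0) ? st.safety * std::pow(errnorm, -0.2) : 5.0;
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    hstep = std::min(st.hmax, std::max(st.hmin, hstep * fac));
  }
  return true;
}

Settings settings_from(double rtol, double atol, double h0, double hmin,
                       double hmax, double safety, int max_steps) {
  Settings st;
  st.rtol = rtol; st.atol = atol; st.h0 = h0; st.hmin = hmin;
  st.hmax = hmax; st.safety = safety; st.max_steps = max_steps;
  return st;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_derivs(NumericVector theta, NumericVector state) {
  Model m = unpack(theta.begin());
  const int n = m.M + 2;
  if (state.size() != n) stop("state has length %d, expected %d", (int)state.size(), n);
  NumericVector out(n);
  rhs(m, state.begin(), out.begin());
  return out;
}

// [[Rcpp::export]]
List cpp_integrate(NumericVector theta, NumericVector state0, double t0, double t1,
                   double rtol, double atol, double h0, double hmin, double hmax,
                   double safety, int max_steps) {
  Model m = unpack(theta.begin());
  const int n = m.M + 2;
  if (state0.size() != n) stop("state0 has length %d, expected %d", (int)state0.size(), n);
  std::vector<double> y(state0.begin(), state0.end());
  Settings st = settings_from(rtol, atol, h0, hmin, hmax, safety, max_steps);
  Recorder rec;
  double t_fail = NA_REAL;
  int iout = 0;
  bool ok = integrate_core(m, y, t0, t1, st, &rec, nullptr, 0, nullptr, iout, &t_fail);

  const int ns = rec.t.size();
  NumericVector times(rec.t.begin(), rec.t.end());
  NumericMatrix states(ns, n), derivs(ns, n);
  for (int k = 0; k < ns; ++k)
    for (int i = 0; i < n; ++i) {
      states(k, i) = rec.y[k * n + i];
      derivs(k, i) = rec.dy[k * n + i];
    }
  return List::create(_["times"] = times, _["states"] = states,
                      _["derivs"] = derivs, _["ok"] = ok, _["t_fail"] = t_fail);
}

// Simulate the observable CI at sorted times `tout`, starting from cancer
// split y0 at t0 with no T cells; if `t_treat` is finite and less than the
// final output time, x_A jumps to xA0 there (x_E to 0).  Built for the
// least-squares inner loop: no trajectory storage.
// [[Rcpp::export]]
List cpp_ci_at(NumericVector theta, NumericVector y0, double t0, double t_treat,
               double xA0, NumericVector tout, double rtol, double atol, double h0,
               double hmin, double hmax, double safety, int max_steps) {
  Model m = unpack(theta.begin());
  const int n = m.M + 2;
  if (y0.size() != m.M) stop("y0 has length %d, expected M=%d", (int)y0.size(), m.M);
  const int nout = tout.size();
  NumericVector ci(nout);
  std::vector<double> y(n, 0.0);
  for (int i = 0; i < m.M; ++i) y[i] = y0[i];

  Settings st = settings_from(rtol, atol, h0, hmin, hmax, safety, max_steps);
  double t_fail = NA_REAL;
  int iout = 0;
  const double t_end = nout > 0 ? tout[nout - 1] : t0;
  const bool treat = R_finite(t_treat) && t_treat > t0 && t_treat < t_end;

  bool ok = true;
  if (treat) {
    ok = integrate_core(m, y, t0, t_treat, st, nullptr, tout.begin(), nout, ci.begin(),
                        iout, &t_fail);
    if (ok) {
      y[m.M] = xA0;
      y[m.M + 1] = 0.0;
      ok = integrate_core(m, y, t_treat, t_end, st, nullptr, tout.begin(), nout,
                          ci.begin(), iout, &t_fail);
    }
  } else if (t_end > t0) {
    ok = integrate_core(m, y, t0, t_end, st, nullptr, tout.begin(), nout, ci.begin(),
                        iout, &t_fail);
  } else {
    while (iout < nout) {
      double s = 0.0;
      for (int i = 0; i < m.M; ++i) s += y[i];
      ci[iout++] = s;
    }
  }
  return List::create(_["ci"] = ci, _["ok"] = ok, _["t_fail"] = t_fail);
}
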