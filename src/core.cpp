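// Simulation core: Hill-type muscle curves, coupled muscle-joint ODE,
// adaptive Runge-Kutta-Fehlberg 4(5) integration with cubic-Hermite dense
// output, and the backward adjoint solve with analytic Jacobians.
//
// State layout: y = [l_1 .. l_m, theta, theta_dot]  (dim m + 2).
// Muscle parameter matrix MP, one row per muscle, columns:
//   0 l_star  1 f_max  2 l_slack  3 moment_arm  4 cos_penn  5 l_mt0
//   6 gamma   7 k_pe   8 eps_pe   9 f_toe      10 k_toe    11 k_lin
//  12 eps_toe 13 V_max 14 b_fv   15 theta_r
// Exo parameter vector EP: 0 J  1 B  2 K  3 tau_g  4 theta_r.
// Lengths in meters, angles in radians, time in seconds.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------- curves

static inline double fl_active(double l, double gamma) {
  double d = l - 1.0;
  return std::exp(-d * d / gamma);
}
static inline double fl_active_d(double l, double gamma) {
  double d = l - 1.0;
  return -2.0 * d / gamma * std::exp(-d * d / gamma);
}
static inline double fpe_passive(double l, double k, double eps) {
  return (std::exp(k * (l - 1.0) / eps) - 1.0) / (std::exp(k) - 1.0);
}
static inline double fpe_passive_d(double l, double k, double eps) {
  return k / eps * std::exp(k * (l - 1.0) / eps) / (std::exp(k) - 1.0);
}
static inline double fse_tendon(double strain, double ftoe, double ktoe,
                                double klin, double epstoe) {
  if (strain <= 0.0) return 0.0;
  if (strain <= epstoe)
    return ftoe * (std::exp(ktoe * strain / epstoe) - 1.0) /
           (std::exp(ktoe) - 1.0);
  return klin * (strain - epstoe) + ftoe;
}
static inline double fse_tendon_d(double strain, double ftoe, double ktoe,
                                  double klin, double epstoe) {
  if (strain <= 0.0) return 0.0;
  if (strain <= epstoe)
    return ftoe * ktoe / epstoe * std::exp(ktoe * strain / epstoe) /
           (std::exp(ktoe) - 1.0);
  return klin;
}

// [[Rcpp::export]]
NumericVector cpp_fl_active(NumericVector l, double gamma) {
  NumericVector out(l.size());
  for (R_xlen_t i = 0; i < l.size(); ++i) out[i] = fl_active(l[i], gamma);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_fpe_passive(NumericVector l, double k, double eps) {
  NumericVector out(l.size());
  for (R_xlen_t i = 0; i < l.size(); ++i) out[i] = fpe_passive(l[i], k, eps);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_fse_tendon(NumericVector strain, double ftoe, double ktoe,
                             double klin, double epstoe) {
  NumericVector out(strain.size());
  for (R_xlen_t i = 0; i < strain.size(); ++i)
    out[i] = fse_tendon(strain[i], ftoe, ktoe, klin, epstoe);
  return out;
}

// ------------------------------------------------- time-series interpolant

struct GridInterp {           // linear interpolation, clamped at both ends
  std::vector<double> t;
  std::vector<std::vector<double> > v;   // v[col][row]
  int ncol;
  void init(const NumericVector& tt, const NumericMatrix& vv) {
    t.assign(tt.begin(), tt.end());
    ncol = vv.ncol();
    v.assign(ncol, std::vector<double>(vv.nrow()));
    for (int c = 0; c < ncol; ++c)
      for (int r = 0; r < vv.nrow(); ++r) v[c][r] = vv(r, c);
  }
  void eval(double tq, double* out) const {
    size_t n = t.size();
    if (n == 1) { for (int c = 0; c < ncol; ++c) out[c] = v[c][0]; return; }
    if (tq <= t.front()) { for (int c = 0; c < ncol; ++c) out[c] = v[c].front(); return; }
    if (tq >= t.back())  { for (int c = 0; c < ncol; ++c) out[c] = v[c].back();  return; }
    size_t i = std::upper_bound(t.begin(), t.end(), tq) - t.begin() - 1;
    double w = (tq - t[i]) / (t[i + 1] - t[i]);
    for (int c = 0; c < ncol; ++c)
      out[c] = (1.0 - w) * v[c][i] + w * v[c][i + 1];
  }
};

// ------------------------------------------------------------- the model

struct Model {
  int m;                       // number of muscles
  NumericMatrix MP;
  double J, B, K, tau_g, theta_r;
  GridInterp act;              // m columns
  GridInterp tau_e;            // 1 column
  bool has_tau_e;

  int dim() const { return m + 2; }

  // rhs; optionally also the state Jacobian A (row-major dim x dim) and the
  // parameter partials dfdp (3m entries: for each muscle, d/d{l_star,
  // f_max, l_slack} stacked as [vj-row entries and thetadd-row entries]).
  // Apack layout (sparse): per muscle j: dvdl[j], dvdth[j], dthdd_dl[j];
  // plus dthdd_dth, dthdd_dthd.
  void rhs(double t, const double* y, double* dy,
           bool want_jac = false,
           double* dvdl = 0, double* dvdth = 0, double* dthdd_dl = 0,
           double* dthdd_dth = 0, double* dthdd_dthd = 0,
           double* dv_dp = 0, double* dthdd_dp = 0) const {
    std::vector<double> a(std::max(m, 1));
    if (m > 0) act.eval(t, a.data());
    double theta = y[m], thetad = y[m + 1];
    double te = 0.0;
    if (has_tau_e) tau_e.eval(t, &te);
    double tau_h = 0.0;
    double sum_dthdd_dth = 0.0;
    for (int j = 0; j < m; ++j) {
      double ls = MP(j, 0), fmax = MP(j, 1), lsl = MP(j, 2), r = MP(j, 3),
             c = MP(j, 4), lmt0 = MP(j, 5), gamma = MP(j, 6), kpe = MP(j, 7),
             epspe = MP(j, 8), ftoe = MP(j, 9), ktoe = MP(j, 10),
             klin = MP(j, 11), epstoe = MP(j, 12), vmax = MP(j, 13),
             b = MP(j, 14), thr = MP(j, 15);
      double l = y[j];
      double aj = std::min(std::max(a[j], 0.0), 1.0);
      double lmt = lmt0 - r * (theta - thr);
      double lt = lmt - ls * l * c;
      double strain = (lt - lsl) / lsl;
      double fse = fse_tendon(strain, ftoe, ktoe, klin, epstoe);
      double fpe = fpe_passive(l, kpe, epspe);
      double fce_raw = fse / c - fpe;
      bool clamped = fce_raw < 0.0;
      double fce = clamped ? 0.0 : fce_raw;
      double fl = fl_active(l, gamma);
      double s = 0.25 + 0.75 * aj;
      dy[j] = s * vmax * (fce - aj * fl) / b;
      tau_h += r * fmax * fse;
      if (want_jac) {
        double fsed = fse_tendon_d(strain, ftoe, ktoe, klin, epstoe);
        double de_dl = -ls * c / lsl;
        double de_dth = -r / lsl;
        double de_dls = -l * c / lsl;
        double de_dlsl = -(strain + 1.0) / lsl;
        double dfce_dl  = clamped ? 0.0 : (fsed * de_dl / c - fpe_passive_d(l, kpe, epspe));
        double dfce_dth = clamped ? 0.0 : (fsed * de_dth / c);
        double dfce_dls = clamped ? 0.0 : (fsed * de_dls / c);
        double dfce_dlsl= clamped ? 0.0 : (fsed * de_dlsl / c);
        double sv = s * vmax / b;
        dvdl[j]  = sv * (dfce_dl - aj * fl_active_d(l, gamma));
        dvdth[j] = sv * dfce_dth;
        dthdd_dl[j] = r * fmax * fsed * de_dl / J;
        sum_dthdd_dth += r * fmax * fsed * de_dth;
        // parameter partials: order per muscle {l_star, f_max, l_slack}
        dv_dp[3 * j + 0] = sv * dfce_dls;
        dv_dp[3 * j + 1] = 0.0;
        dv_dp[3 * j + 2] = sv * dfce_dlsl;
        dthdd_dp[3 * j + 0] = r * fmax * fsed * de_dls / J;
        dthdd_dp[3 * j + 1] = r * fse / J;
        dthdd_dp[3 * j + 2] = r * fmax * fsed * de_dlsl / J;
      }
    }
    dy[m] = thetad;
    dy[m + 1] = (tau_h + te - B * thetad - K * (theta - theta_r) -
                 tau_g * std::sin(theta - theta_r)) / J;
    if (want_jac) {
      *dthdd_dth = (sum_dthdd_dth - K - tau_g * std::cos(theta - theta_r)) / J;
      *dthdd_dthd = -B / J;
    }
  }

  double torque(double t, const double* y) const {
    double tau_h = 0.0;
    std::vector<double> a(std::max(m, 1));
    if (m > 0) act.eval(t, a.data());
    double theta = y[m];
    for (int j = 0; j < m; ++j) {
      double ls = MP(j, 0), fmax = MP(j, 1), lsl = MP(j, 2), r = MP(j, 3),
             c = MP(j, 4), lmt0 = MP(j, 5), thr = MP(j, 15);
      double lt = lmt0 - r * (theta - thr) - ls * y[j] * c;
      double strain = (lt - lsl) / lsl;
      tau_h += r * fmax * fse_tendon(strain, MP(j, 9), MP(j, 10), MP(j, 11),
                                     MP(j, 12));
    }
    return tau_h;
  }
};

static Model build_model(const NumericMatrix& MP, const NumericVector& EP,
                         const NumericVector& act_t, const NumericMatrix& act_v,
                         const NumericVector& tau_e_t,
                         const NumericVector& tau_e_v) {
  Model mod;
  mod.m = MP.nrow();
  mod.MP = MP;
  mod.J = EP[0]; mod.B = EP[1]; mod.K = EP[2];
  mod.tau_g = EP[3]; mod.theta_r = EP[4];
  if (mod.m > 0) mod.act.init(act_t, act_v);
  mod.has_tau_e = tau_e_v.size() > 0 &&
                  !(tau_e_v.size() == 1 && tau_e_v[0] == 0.0);
  if (mod.has_tau_e) {
    NumericMatrix tv(tau_e_v.size(), 1);
    for (R_xlen_t i = 0; i < tau_e_v.size(); ++i) tv(i, 0) = tau_e_v[i];
    mod.tau_e.init(tau_e_t, tv);
  }
  return mod;
}

// -------------------------------------------------------- RKF45 stepper

struct Dense {                 // accepted-step nodes for Hermite interp
  std::vector<double> t;
  std::vector<std::vector<double> > y, f;   // [node][dim]
};

// Fehlberg 4(5) coefficients
static const double A21 = 1.0 / 4.0;
static const double A31 = 3.0 / 32.0, A32 = 9.0 / 32.0;
static const double A41 = 1932.0 / 2197.0, A42 = -7200.0 / 2197.0,
                    A43 = 7296.0 / 2197.0;
static const double A51 = 439.0 / 216.0, A52 = -8.0, A53 = 3680.0 / 513.0,
                    A54 = -845.0 / 4104.0;
static const double A61 = -8.0 / 27.0, A62 = 2.0, A63 = -3544.0 / 2565.0,
                    A64 = 1859.0 / 4104.0, A65 = -11.0 / 40.0;
static const double C2 = 0.25, C3 = 0.375, C4 = 12.0 / 13.0, C5 = 1.0,
                    C6 = 0.5;
static const double B5[6] = {16.0 / 135.0, 0.0, 6656.0 / 12825.0,
                             28561.0 / 56430.0, -9.0 / 50.0, 2.0 / 55.0};
static const double B4[6] = {25.0 / 216.0, 0.0, 1408.0 / 2565.0,
                             2197.0 / 4104.0, -1.0 / 5.0, 0.0};

template <class RHS>
static void rkf45(RHS rhs, int dim, double t0, double t1,
                  std::vector<double>& y, double rtol, double atol,
                  double fixed_step, Dense* dense) {
  double dir = (t1 >= t0) ? 1.0 : -1.0;
  double span = std::fabs(t1 - t0);
  if (span <= 0.0) return;
  double h = (fixed_step > 0.0) ? dir * fixed_step : dir * span * 1e-3;
  double hmin = span * 1e-12;
  double t = t0;
  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), k5(dim), k6(dim),
      ytmp(dim), y5(dim), y4(dim);
  rhs(t, y.data(), k1.data());
  if (dense) {
    dense->t.push_back(t);
    dense->y.push_back(y);
    dense->f.push_back(k1);
  }
  int maxsteps = 10000000;
  while (dir * (t1 - t) > 1e-14 * span && maxsteps-- > 0) {
    if (dir * (t + h - t1) > 0.0) h = t1 - t;
    for (int i = 0; i < dim; ++i) ytmp[i] = y[i] + h * A21 * k1[i];
    rhs(t + C2 * h, ytmp.data(), k2.data());
    for (int i = 0; i < dim; ++i)
      ytmp[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
    rhs(t + C3 * h, ytmp.data(), k3.data());
    for (int i = 0; i < dim; ++i)
      ytmp[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
    rhs(t + C4 * h, ytmp.data(), k4.data());
    for (int i = 0; i < dim; ++i)
      ytmp[i] = y[i] + h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] +
                            A54 * k4[i]);
    rhs(t + C5 * h, ytmp.data(), k5.data());
    for (int i = 0; i < dim; ++i)
      ytmp[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] +
                            A64 * k4[i] + A65 * k5[i]);
    rhs(t + C6 * h, ytmp.data(), k6.data());
    double errnorm = 0.0;
    for (int i = 0; i < dim; ++i) {
      y5[i] = y[i] + h * (B5[0] * k1[i] + B5[2] * k3[i] + B5[3] * k4[i] +
                          B5[4] * k5[i] + B5[5] * k6[i]);
      y4[i] = y[i] + h * (B4[0] * k1[i] + B4[2] * k3[i] + B4[3] * k4[i] +
                          B4[4] * k5[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double e = (y5[i] - y4[i]) / sc;
      errnorm += e * e;
    }
    errnorm = std::sqrt(errnorm / dim);
    bool finite_err = std::isfinite(errnorm);
    bool accept = (fixed_step > 0.0) || (finite_err && errnorm <= 1.0);
    if (!accept && std::fabs(h) <= hmin * 1.0001) {
      // at the smallest representable step: push through mild roughness,
      // fail hard on hopeless (non-finite or wildly out-of-tolerance) steps
      if (finite_err && errnorm < 100.0) accept = true;
      else stop("RKF45 step size underflow at t = %g", t);
    }
    if (accept) {
      t += h;
      y = y5;
      rhs(t, y.data(), k1.data());   // FSAL-style refresh for next step
      if (dense) {
        dense->t.push_back(t);
        dense->y.push_back(y);
        dense->f.push_back(k1);
      }
    }
    if (fixed_step <= 0.0) {
      double fac;
      if (!finite_err) fac = 0.2;
      else if (errnorm > 1e-300) fac = 0.9 * std::pow(errnorm, -0.2);
      else fac = 5.0;
      fac = std::min(5.0, std::max(0.2, fac));
      h *= fac;
      if (std::fabs(h) < hmin) h = dir * hmin;
    }
  }
  if (maxsteps <= 0) stop("RKF45 exceeded the maximum number of steps");
}

// cubic Hermite interpolation on dense nodes (monotone node sequence in
// the direction of integration)
struct HermiteInterp {
  const Dense* d;
  bool forward;
  explicit HermiteInterp(const Dense* dd) : d(dd) {
    forward = d->t.size() < 2 || d->t[1] >= d->t[0];
  }
  void eval(double tq, double* out, int dim) const {
    size_t n = d->t.size();
    size_t i;
    if (forward) {
      if (tq <= d->t.front()) i = 0;
      else if (tq >= d->t.back()) i = n - 2;
      else i = std::upper_bound(d->t.begin(), d->t.end(), tq) -
               d->t.begin() - 1;
    } else {
      if (tq >= d->t.front()) i = 0;
      else if (tq <= d->t.back()) i = n - 2;
      else i = std::upper_bound(d->t.begin(), d->t.end(), tq,
                                std::greater<double>()) - d->t.begin() - 1;
    }
    double h = d->t[i + 1] - d->t[i];
    double s = (tq - d->t[i]) / h;
    double h00 = (1 + 2 * s) * (1 - s) * (1 - s);
    double h10 = s * (1 - s) * (1 - s);
    double h01 = s * s * (3 - 2 * s);
    double h11 = s * s * (s - 1);
    for (int c = 0; c < dim; ++c)
      out[c] = h00 * d->y[i][c] + h * h10 * d->f[i][c] +
               h01 * d->y[i + 1][c] + h * h11 * d->f[i + 1][c];
  }
};

// ------------------------------------------------------------ simulate

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix MP, NumericVector EP,
                  NumericVector act_t, NumericMatrix act_v,
                  NumericVector tau_e_t, NumericVector tau_e_v,
                  NumericVector state0, NumericVector tout,
                  double rtol, double atol, double fixed_step,
                  bool keep_dense) {
  Model mod = build_model(MP, EP, act_t, act_v, tau_e_t, tau_e_v);
  int dim = mod.dim();
  if (state0.size() != dim) stop("state0 has wrong length");
  std::vector<double> y(state0.begin(), state0.end());
  Dense dense;
  auto rhs = [&](double t, const double* yy, double* dyy) {
    mod.rhs(t, yy, dyy);
  };
  double t0 = tout[0], t1 = tout[tout.size() - 1];
  rkf45(rhs, dim, t0, t1, y, rtol, atol, fixed_step, &dense);
  HermiteInterp hi(&dense);
  NumericMatrix yout(tout.size(), dim);
  NumericVector tau_h(tout.size());
  std::vector<double> buf(dim);
  for (R_xlen_t i = 0; i < tout.size(); ++i) {
    hi.eval(tout[i], buf.data(), dim);
    for (int c = 0; c < dim; ++c) yout(i, c) = buf[c];
    tau_h[i] = mod.torque(tout[i], buf.data());
  }
  List out = List::create(_["tout"] = tout, _["y"] = yout,
                          _["tau_h"] = tau_h,
                          _["n_steps"] = (int)dense.t.size() - 1);
  if (keep_dense) {
    int nn = dense.t.size();
    NumericVector dt(nn);
    NumericMatrix dy(nn, dim), df(nn, dim);
    for (int i = 0; i < nn; ++i) {
      dt[i] = dense.t[i];
      for (int c = 0; c < dim; ++c) {
        dy(i, c) = dense.y[i][c];
        df(i, c) = dense.f[i][c];
      }
    }
    out["dense_t"] = dt;
    out["dense_y"] = dy;
    out["dense_f"] = df;
  }
  return out;
}

// ------------------------------------------------------------- adjoint

// Backward solve of  dlambda/dt = -A(t)^T lambda  with per-sample jumps
// 2 w_i (zdot_i - thetadot_meas_i) added to the theta_dot component at the
// measurement times, and gradient accumulators dG/dt = -lambda^T df/dp.
// Returns dLoss/dp for p = {l_star, f_max, l_slack} per muscle (3m).
// [[Rcpp::export]]
List cpp_adjoint(NumericMatrix MP, NumericVector EP,
                 NumericVector act_t, NumericMatrix act_v,
                 NumericVector tau_e_t, NumericVector tau_e_v,
                 NumericVector dense_t, NumericMatrix dense_y,
                 NumericMatrix dense_f,
                 NumericVector meas_t, NumericVector meas_w,
                 NumericVector zdot_pred, NumericVector thetadot_meas,
                 double rtol, double atol) {
  Model mod = build_model(MP, EP, act_t, act_v, tau_e_t, tau_e_v);
  int m = mod.m, dim = mod.dim(), np = 3 * m;
  int N = meas_t.size();
  if (N < 2) stop("need at least two measurement samples");

  Dense fwd;                       // rebuild dense struct for interpolation
  fwd.t.assign(dense_t.begin(), dense_t.end());
  int nn = dense_t.size();
  fwd.y.assign(nn, std::vector<double>(dim));
  fwd.f.assign(nn, std::vector<double>(dim));
  for (int i = 0; i < nn; ++i)
    for (int c = 0; c < dim; ++c) {
      fwd.y[i][c] = dense_y(i, c);
      fwd.f[i][c] = dense_f(i, c);
    }
  HermiteInterp hi(&fwd);

  std::vector<double> x(dim), dy(dim);
  std::vector<double> dvdl(std::max(m, 1)), dvdth(std::max(m, 1)),
      dthdd_dl(std::max(m, 1)), dv_dp(std::max(np, 1)),
      dthdd_dp(std::max(np, 1));
  double dthdd_dth, dthdd_dthd;

  // augmented backward state: [lambda (dim), G (np)]
  auto rhs = [&](double t, const double* z, double* dz) {
    hi.eval(t, x.data(), dim);
    mod.rhs(t, x.data(), dy.data(), true, dvdl.data(), dvdth.data(),
            dthdd_dl.data(), &dthdd_dth, &dthdd_dthd, dv_dp.data(),
            dthdd_dp.data());
    const double* lam = z;
    double lam_th = lam[m], lam_thd = lam[m + 1];
    for (int j = 0; j < m; ++j)
      dz[j] = -(dvdl[j] * lam[j] + dthdd_dl[j] * lam_thd);
    double acc = dthdd_dth * lam_thd;
    for (int j = 0; j < m; ++j) acc += dvdth[j] * lam[j];
    dz[m] = -acc;
    dz[m + 1] = -(lam_th + dthdd_dthd * lam_thd);
    for (int p = 0; p < np; ++p) {
      int j = p / 3;
      double q = lam[j] * dv_dp[p] + lam_thd * dthdd_dp[p];
      dz[dim + p] = -q;
    }
  };

  std::vector<double> z(dim + np, 0.0);
  double loss = 0.0;
  for (int i = 0; i < N; ++i) {
    double r = zdot_pred[i] - thetadot_meas[i];
    loss += meas_w[i] * r * r;
  }
  // sweep backward over measurement segments
  for (int i = N - 1; i >= 1; --i) {
    double r = zdot_pred[i] - thetadot_meas[i];
    z[m + 1] += 2.0 * meas_w[i] * r;          // jump on theta_dot adjoint
    rkf45(rhs, dim + np, meas_t[i], meas_t[i - 1], z, rtol, atol, -1.0,
          (Dense*)0);
  }
  // jump at t_0 would multiply d(state0)/dp = 0: no contribution.
  NumericVector grad(np);
  for (int p = 0; p < np; ++p) grad[p] = z[dim + p];
  NumericVector lam0(dim);
  for (int c = 0; c < dim; ++c) lam0[c] = z[c];
  return List::create(_["gradient"] = grad, _["loss"] = loss,
                      _["lambda0"] = lam0);
}
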