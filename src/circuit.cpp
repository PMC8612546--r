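#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Reduced-form transient dynamics in normalized units (sigma = 1, m_e = m_i = 1,
// A_max = 1). The inhibitory unit relaxes exponentially and is known in closed
// form on a constant-input segment; only the excitatory equation
//   tau_e * da/dt = -a + alpha_e * I_post / (A_i(t) + 1)
// is integrated, with a classical fixed-step RK4 scheme. Attention enters as
// multiplicative gains alpha_e (excitatory input) and alpha_i (inhibitory
// input); alpha_e = alpha_i = 1 recovers the plain circuit.
//
// p, q are the *unattended* normalized sustained activations before/after the
// change; the corresponding normalized inputs are I = a / (1 - a).

struct ReducedDrive {
  double eIpost;   // alpha_e * I_post
  double aIpost;   // alpha_i * I_post  (asymptotic inhibition)
  double dI;       // alpha_i * (I_pre - I_post)
  double tau_i;
  double drive(double expfac) const {
    // expfac = exp(-t / tau_i)
    return eIpost / (aIpost + dI * expfac + 1.0);
  }
};

// integrate from t = 0 (the change) with initial value a0, step dt, n steps;
// returns a on the internal grid 0, dt, ..., n*dt
static std::vector<double> rk4_reduced(const ReducedDrive &d, double a0,
                                       double tau_e, double dt, int n) {
  std::vector<double> a(n + 1);
  a[0] = a0;
  const double ef = std::exp(-dt / d.tau_i);
  const double efh = std::exp(-0.5 * dt / d.tau_i);
  double E = 1.0; // exp(-t/tau_i) at current step
  double x = a0;
  for (int k = 0; k < n; ++k) {
    double Eh = E * efh, E1 = E * ef;
    double D0 = d.drive(E), Dh = d.drive(Eh), D1 = d.drive(E1);
    double k1 = (-x + D0) / tau_e;
    double x2 = x + 0.5 * dt * k1;
    double k2 = (-x2 + Dh) / tau_e;
    double x3 = x + 0.5 * dt * k2;
    double k3 = (-x3 + Dh) / tau_e;
    double x4 = x + dt * k3;
    double k4 = (-x4 + D1) / tau_e;
    x += dt * (k1 + 2.0 * k2 + 2.0 * k3 + k4) / 6.0;
    E = E1;
    a[k + 1] = x;
  }
  return a;
}

static ReducedDrive make_drive(double p, double q, double tau_i,
                               double alpha_e, double alpha_i) {
  double Ipre = p / (1.0 - p), Ipost = q / (1.0 - q);
  ReducedDrive d;
  d.eIpost = alpha_e * Ipost;
  d.aIpost = alpha_i * Ipost;
  d.dI = alpha_i * (Ipre - Ipost);
  d.tau_i = tau_i;
  return d;
}

// attended pre-change steady state: alpha_e*I / (alpha_i*I + 1)
static double steady_norm(double a, double alpha_e, double alpha_i) {
  double I = a / (1.0 - a);
  return alpha_e * I / (alpha_i * I + 1.0);
}

// [[Rcpp::export]]
NumericVector cpp_reduced_ae(double p, double q, double tau_e, double tau_i,
                             double alpha_e, double alpha_i,
                             NumericVector t_out, double dt) {
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1)
    stop("normalized activations must lie strictly inside (0, 1)");
  int m = t_out.size();
  double tmax = 0.0;
  for (int i = 0; i < m; ++i) {
    if (t_out[i] < 0) stop("t_out must be >= 0 (0 = change time)");
    if (t_out[i] > tmax) tmax = t_out[i];
  }
  ReducedDrive d = make_drive(p, q, tau_i, alpha_e, alpha_i);
  double a0 = steady_norm(p, alpha_e, alpha_i);
  int n = std::max(1, (int)std::ceil(tmax / dt));
  double h = (tmax > 0.0) ? tmax / n : dt;
  std::vector<double> a = rk4_reduced(d, a0, tau_e, h, n);
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double u = t_out[i] / h;
    int k = (int)std::floor(u);
    if (k >= n) { out[i] = a[n]; continue; }
    double w = u - k;
    out[i] = (1.0 - w) * a[k] + w * a[k + 1];
  }
  return out;
}

// Full circuit, general parameters, piecewise-constant input.
// seg_t: segment start times (first must equal t_out start boundary t0),
// seg_I: input value on each segment. Initial conditions Ae0, Ai0 at t0.
// A_i has the closed form gi + (Ai(t0seg) - gi) * exp(-(t - t0seg)/tau_i)
// on each segment; A_e is advanced by RK4 with step dt.
// [[Rcpp::export]]
List cpp_full_circuit(double tau_e, double tau_i, double m_e, double m_i,
                      double sigma, double theta_e, double theta_i,
                      NumericVector seg_t, NumericVector seg_I,
                      double Ae0, double Ai0,
                      NumericVector t_out, double dt) {
  int ns = seg_t.size();
  if (ns < 1 || seg_I.size() != ns) stop("segment times/values mismatch");
  int m = t_out.size();
  NumericVector Ae(m), Ai(m);
  double t = seg_t[0];
  double ae = Ae0, ai = Ai0;
  int iout = 0;
  double t_prev = t, ae_prev = ae, ai_prev = ai;
  // emit requested times in (t_prev, tcur] by linear interpolation
  auto emit = [&](double tcur, double aev, double aiv) {
    while (iout < m && t_out[iout] <= tcur + 1e-12) {
      double w = (tcur > t_prev) ?
        (t_out[iout] - t_prev) / (tcur - t_prev) : 1.0;
      if (w < 0) w = 0;
      if (w > 1) w = 1;
      double aeo = (1.0 - w) * ae_prev + w * aev;
      Ae[iout] = aeo < 0 ? 0 : aeo;
      Ai[iout] = (1.0 - w) * ai_prev + w * aiv;
      ++iout;
    }
    t_prev = tcur;
    ae_prev = aev;
    ai_prev = aiv;
  };
  emit(t, ae, ai);
  for (int s = 0; s < ns; ++s) {
    double tend = (s + 1 < ns) ? seg_t[s + 1] : t_out[m - 1];
    if (tend <= t) continue;
    double I = seg_I[s];
    double gi = (I > theta_i) ? m_i * (I - theta_i) : 0.0;
    double ai_start = ai;
    double t0 = t;
    int n = std::max(1, (int)std::ceil((tend - t) / dt));
    double h = (tend - t) / n;
    const double ef = std::exp(-h / tau_i);
    const double efh = std::exp(-0.5 * h / tau_i);
    double E = 1.0;
    for (int k = 0; k < n; ++k) {
      double Eh = E * efh, E1 = E * ef;
      double dAi = ai_start - gi;
      auto drive = [&](double expfac) {
        double aival = gi + dAi * expfac;
        double x = I / (aival + sigma);
        return (x > theta_e) ? m_e * (x - theta_e) : 0.0;
      };
      double D0 = drive(E), Dh = drive(Eh), D1 = drive(E1);
      double k1 = (-ae + D0) / tau_e;
      double x2 = ae + 0.5 * h * k1;
      double k2 = (-x2 + Dh) / tau_e;
      double x3 = ae + 0.5 * h * k2;
      double k3 = (-x3 + Dh) / tau_e;
      double x4 = ae + h * k3;
      double k4 = (-x4 + D1) / tau_e;
      ae += h * (k1 + 2.0 * k2 + 2.0 * k3 + k4) / 6.0;
      E = E1;
      t = t0 + (k + 1) * h;
      ai = gi + dAi * E;
      emit(t, ae, ai);
    }
  }
  // any trailing requested times (numerical edge)
  while (iout < m) { Ae[iout] = ae < 0 ? 0 : ae; Ai[iout] = ai; ++iout; }
  return List::create(_["A_e"] = Ae, _["A_i"] = Ai);
}

// Exhaustive chi-square evaluation of the reduced model over a 3-D
// (tau_e, tau_i, A_max) grid against a binned PSTH. Model time 0 is response
// onset; the model is averaged within each PSTH bin (downsampling) before the
// squared error is taken. Returns chi2 values in grid order with tau_e the
// fastest index: idx = ie + ne*(ii + ni*ia).
// [[Rcpp::export]]
NumericVector cpp_grid_chi2(double Apre, double Apost,
                            NumericVector taue, NumericVector taui,
                            NumericVector amax,
                            NumericVector rate, NumericVector sem2,
                            NumericVector bin_lo, NumericVector bin_hi,
                            int min_substeps) {
  int ne = taue.size(), ni = taui.size(), na = amax.size();
  int nb = rate.size();
  if (sem2.size() != nb || bin_lo.size() != nb || bin_hi.size() != nb)
    stop("bin vectors mismatch");
  double tmax = bin_hi[nb - 1];
  NumericVector chi2(ne * ni * na);
  for (int ia = 0; ia < na; ++ia) {
    double A = amax[ia];
    double p = Apre / A, q = Apost / A;
    bool bad = (p <= 0 || p >= 1 || q <= 0 || q >= 1);
    for (int ii = 0; ii < ni; ++ii) {
      for (int ie = 0; ie < ne; ++ie) {
        int idx = ie + ne * (ii + ni * ia);
        if (bad) { chi2[idx] = R_PosInf; continue; }
        double te = taue[ie], ti = taui[ii];
        double dt = std::min(te, ti) / 20.0;
        int n = std::max(min_substeps, (int)std::ceil(tmax / dt));
        double h = tmax / n;
        ReducedDrive d = make_drive(p, q, ti, 1.0, 1.0);
        std::vector<double> a = rk4_reduced(d, p, te, h, n);
        // average model within bins (trapezoid over internal grid)
        double acc = 0.0;
        for (int b = 0; b < nb; ++b) {
          double lo = bin_lo[b], hi = bin_hi[b];
          int k0 = (int)std::floor(lo / h), k1 = (int)std::ceil(hi / h);
          if (k1 > n) k1 = n;
          if (k0 < 0) k0 = 0;
          double s = 0.0; int cnt = 0;
          for (int k = k0; k <= k1; ++k) {
            double tk = k * h;
            if (tk >= lo - 1e-12 && tk <= hi + 1e-12) { s += a[k]; ++cnt; }
          }
          double model = (cnt > 0) ? A * s / cnt : A * a[std::min(n, k0)];
          double dev = model - rate[b];
          acc += dev * dev / sem2[b];
        }
        chi2[idx] = acc / nb;
      }
    }
  }
  return chi2;
}
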