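// Symmetric Steinecke-Herzel two-mass vocal-fold model: fixed-step RK4
// integrator plus small numeric kernels used by the measures layer.
// Units throughout: g-cm-ms (pressures g cm^-1 ms^-2, flows cm^3 ms^-1).

#include <Rcpp.h>
#include <cmath>

// The integrator is latency-bound scalar arithmetic; O3 roughly halves the
// per-simulation cost with this toolchain and population runs involve tens
// of thousands of simulations.
#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3")
#endif

using namespace Rcpp;

// Parameter vector layout (must match param_names() on the R side).
enum ParIdx {
  iP = 0, im1, im2, ik1, ik2, ikc, ir1, ir2,
  id1, id2, iL, ic1, ic2, ia01, ia02, ix0
};

// Smoothed Heaviside step: 0 for y <= 0, tanh(50 y / x0) for y > 0.
// tanh saturates to 1 within 1 ulp for arguments above ~19, which covers
// the vast majority of calls during voiced oscillation.
static inline double theta(double y, double x0) {
  if (y <= 0.0) return 0.0;
  const double t = 50.0 * y / x0;
  return (t > 19.0) ? 1.0 : std::tanh(t);
}

struct ShDeriv {
  double k1, k2, kc, r1, r2, a01, a02;
  double twoL;        // 2 L
  double inv_m1, inv_m2;
  double c1_2L, c2_2L;  // c_i / (2 L)
  double Ld1P;        // L d1 P
  double s50;         // 50 / x0 (smoothed-step slope)

  explicit ShDeriv(const NumericVector &p)
    : k1(p[ik1]), k2(p[ik2]), kc(p[ikc]), r1(p[ir1]), r2(p[ir2]),
      a01(p[ia01]), a02(p[ia02]), twoL(2.0 * p[iL]),
      inv_m1(1.0 / p[im1]), inv_m2(1.0 / p[im2]),
      c1_2L(p[ic1] / (2.0 * p[iL])), c2_2L(p[ic2] / (2.0 * p[iL])),
      Ld1P(p[iL] * p[id1] * p[iP]), s50(50.0 / p[ix0]) {}

  // smoothed step with precomputed slope; saturates to 1 above tanh^-1
  // resolution
  inline double th(double y) const {
    if (y <= 0.0) return 0.0;
    const double t = s50 * y;
    return (t > 19.0) ? 1.0 : std::tanh(t);
  }

  inline void operator()(const double s[4], double ds[4]) const {
    const double x1 = s[0], v1 = s[1], x2 = s[2], v2 = s[3];
    const double a1 = a01 + twoL * x1;
    const double a2 = a02 + twoL * x2;
    const double amin = (a1 < a2) ? a1 : a2;

    // Driving pressure on the lower mass: full subglottal pressure when
    // the glottis is closed above, Bernoulli recovery when open
    // (amin <= a1 always, so the ratio is bounded by 1).
    double f_aero = 0.0;
    if (a1 > 0.0) {
      if (amin > 0.0) {
        const double rat = amin / a1;
        f_aero = Ld1P * (1.0 - th(amin) * rat * rat) * th(a1);
      } else {
        f_aero = Ld1P * th(a1);
      }
    }

    const double f1 = f_aero - r1 * v1 - k1 * x1 - kc * (x1 - x2)
                      - th(-a1) * c1_2L * a1;
    const double f2 = -r2 * v2 - k2 * x2 - kc * (x2 - x1)
                      - th(-a2) * c2_2L * a2;

    ds[0] = v1;
    ds[1] = f1 * inv_m1;
    ds[2] = v2;
    ds[3] = f2 * inv_m2;
  }
};

// [[Rcpp::export]]
List cpp_simulate(NumericVector par, double dt, double duration,
                  double transient, double x_init, double v_init,
                  double rho, bool keep_trajectory) {
  const int n_steps = (int)std::llround(duration / dt);
  const int n_skip = (int)std::llround(transient / dt);
  if (n_steps <= 0 || n_skip < 0 || n_skip >= n_steps)
    stop("invalid step counts derived from dt/duration/transient");

  const ShDeriv f(par);
  const double L = par[iL], a01 = par[ia01], a02 = par[ia02];
  const double x0 = par[ix0], P = par[iP];
  const double flow_coef = std::sqrt(2.0 * P / rho);

  const int n_keep = n_steps - n_skip + 1;  // post-transient samples incl. t = transient
  NumericVector u(n_keep);
  double *up = u.begin();

  NumericVector tx1, tv1, tx2, tv2, ta1, ta2, tamin;
  if (keep_trajectory) {
    tx1 = NumericVector(n_steps + 1); tv1 = NumericVector(n_steps + 1);
    tx2 = NumericVector(n_steps + 1); tv2 = NumericVector(n_steps + 1);
    ta1 = NumericVector(n_steps + 1); ta2 = NumericVector(n_steps + 1);
    tamin = NumericVector(n_steps + 1);
  }

  double s[4] = {x_init, v_init, x_init, v_init};
  bool diverged = false;

  double k1v[4], k2v[4], k3v[4], k4v[4], tmp[4];

  for (int step = 0; step <= n_steps; ++step) {
    const double a1 = a01 + 2.0 * L * s[0];
    const double a2 = a02 + 2.0 * L * s[2];
    const double amin = (a1 < a2) ? a1 : a2;

    if (keep_trajectory) {
      tx1[step] = s[0]; tv1[step] = s[1]; tx2[step] = s[2]; tv2[step] = s[3];
      ta1[step] = a1; ta2[step] = a2; tamin[step] = amin;
    }
    if (step >= n_skip)
      up[step - n_skip] = (amin > 0.0) ? flow_coef * amin * theta(amin, x0) : 0.0;

    // divergence check amortized over a short stride; a blow-up is caught
    // within 64 steps (0.64 ms of model time) which is ample for flagging
    if ((step & 63) == 0 &&
        (!(std::isfinite(s[0]) && std::isfinite(s[1]) &&
           std::isfinite(s[2]) && std::isfinite(s[3])) ||
         std::fabs(s[0]) > 1e6 || std::fabs(s[2]) > 1e6)) {
      diverged = true;
      break;
    }
    // fixed-point early exit: the system is autonomous, so once the state
    // sits at numerical equilibrium (velocities and accelerations below
    // threshold) it stays there for the rest of the run; the remaining
    // flow samples are the constant equilibrium flow
    if ((step & 1023) == 0 && step > 0 && !keep_trajectory &&
        std::fabs(s[1]) < 1e-10 && std::fabs(s[3]) < 1e-10) {
      double ds[4];
      f(s, ds);
      if (std::fabs(ds[1]) < 1e-10 && std::fabs(ds[3]) < 1e-10) {
        const double u_eq =
          (amin > 0.0) ? flow_coef * amin * theta(amin, x0) : 0.0;
        for (int k = (step >= n_skip ? step - n_skip : 0); k < n_keep; ++k)
          up[k] = u_eq;
        break;
      }
    }
    if (step == n_steps) break;

    // classical RK4
    f(s, k1v);
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + 0.5 * dt * k1v[j];
    f(tmp, k2v);
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + 0.5 * dt * k2v[j];
    f(tmp, k3v);
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + dt * k3v[j];
    f(tmp, k4v);
    for (int j = 0; j < 4; ++j)
      s[j] += dt / 6.0 * (k1v[j] + 2.0 * k2v[j] + 2.0 * k3v[j] + k4v[j]);
  }

  if (!diverged && !(std::isfinite(s[0]) && std::isfinite(s[1]) &&
                     std::isfinite(s[2]) && std::isfinite(s[3])))
    diverged = true;  // blow-up inside the final check stride

  List out = List::create(
    _["u"] = u,
    _["dt"] = dt,
    _["t_start"] = n_skip * dt,
    _["diverged"] = diverged);
  if (keep_trajectory) {
    out["x1"] = tx1; out["v1"] = tv1; out["x2"] = tx2; out["v2"] = tv2;
    out["a1"] = ta1; out["a2"] = ta2; out["a_min"] = tamin;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_derivatives(NumericVector state, NumericVector par) {
  const ShDeriv f(par);
  double s[4] = {state[0], state[1], state[2], state[3]};
  double ds[4];
  f(s, ds);
  return NumericVector::create(ds[0], ds[1], ds[2], ds[3]);
}

// Upward crossings of thr = min(u) + eps * (max(u) - min(u)). For a
// waveform with full glottal closure (min = 0) this is eps * max(u); for
// oscillation with incomplete closure the threshold rides on the DC
// offset so the cycles are still found. Returns the 1-based index of the
// first sample at/above threshold for each crossing, plus the linear
// interpolation fraction of the crossing position within the preceding
// sample interval.
// [[Rcpp::export]]
List cpp_detect_cycles(NumericVector u, double eps) {
  const int n = u.size();
  const double *up = u.begin();
  double umax = -1e300, umin = 1e300;
  for (int i = 0; i < n; ++i) {
    if (up[i] > umax) umax = up[i];
    if (up[i] < umin) umin = up[i];
  }
  if (!(umax > 0.0) || !(umax > umin))
    return List::create(_["idx"] = IntegerVector(0),
                        _["frac"] = NumericVector(0),
                        _["thr"] = 0.0);
  const double thr = umin + eps * (umax - umin);
  // Hysteresis: a low-threshold crossing only becomes a cycle boundary
  // once the waveform reaches mid-level, so secondary ripples near the
  // trough are not mistaken for pulse onsets.
  const double confirm = umin + 0.5 * (umax - umin);
  std::vector<int> idx;
  std::vector<double> frac;
  int cand = -1;
  double cand_frac = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    const double u0 = up[i], u1 = up[i + 1];
    if (cand < 0 && u0 < thr && u1 >= thr) {
      cand = i + 2;                    // 1-based index of sample above thr
      const double du = u1 - u0;
      cand_frac = du > 0.0 ? (thr - u0) / du : 0.0;
    }
    if (cand >= 0) {
      if (u1 >= confirm) {             // confirmed pulse onset
        idx.push_back(cand);
        frac.push_back(cand_frac);
        cand = -1;
      } else if (u1 < thr) {           // fell back: ripple, not an onset
        cand = -1;
      }
    }
  }
  return List::create(_["idx"] = wrap(idx), _["frac"] = wrap(frac),
                      _["thr"] = thr);
}

// Mean, max and maximum declination rate (centered differences) of
// u[a..b] (1-based inclusive).
// [[Rcpp::export]]
NumericVector cpp_span_stats(NumericVector u, int a, int b, double dt) {
  const double *up = u.begin();
  const int lo = a - 1, hi = b - 1;
  double sum = 0.0, mx = -1e300;
  for (int i = lo; i <= hi; ++i) {
    sum += up[i];
    if (up[i] > mx) mx = up[i];
  }
  double mfdr = -1e300;
  for (int i = lo + 1; i < hi; ++i) {
    const double d = -(up[i + 1] - up[i - 1]) / (2.0 * dt);
    if (d > mfdr) mfdr = d;
  }
  return NumericVector::create(sum / (hi - lo + 1), mx, mfdr);
}

// Goertzel magnitudes |sum_k u_k exp(-i w k)| at the supplied normalized
// angular frequencies (radians per sample), over u[a..b] (1-based).
// [[Rcpp::export]]
NumericVector cpp_goertzel(NumericVector u, NumericVector omegas,
                           int a, int b) {
  const double *up = u.begin();
  const int lo = a - 1, hi = b - 1;
  const int m = omegas.size();
  NumericVector mag(m);
  for (int j = 0; j < m; ++j) {
    const double w = omegas[j];
    const double coef = 2.0 * std::cos(w);
    double s1 = 0.0, s2 = 0.0;
    for (int k = lo; k <= hi; ++k) {
      const double s0 = up[k] + coef * s1 - s2;
      s2 = s1;
      s1 = s0;
    }
    const double re = s1 - s2 * std::cos(w);
    const double im = s2 * std::sin(w);
    mag[j] = std::sqrt(re * re + im * im);
  }
  return mag;
}

// Per-cycle statistics over [start_i, end_i) index ranges (1-based,
// half-open): peak, trough, samples at/above threshold (open), rise
// samples (start -> argmax) and fall samples (argmax -> end) counted
// within the open phase.
// [[Rcpp::export]]
NumericMatrix cpp_cycle_stats(NumericVector u, IntegerVector starts,
                              IntegerVector ends, double thr) {
  const double *up = u.begin();
  const int nc = starts.size();
  NumericMatrix out(nc, 5);
  for (int c = 0; c < nc; ++c) {
    const int a = starts[c] - 1, b = ends[c] - 1;
    double pk = -1e300, tr = 1e300;
    int ipk = a, open_n = 0;
    for (int k = a; k < b; ++k) {
      const double v = up[k];
      if (v > pk) { pk = v; ipk = k; }
      if (v < tr) tr = v;
      if (v >= thr) ++open_n;
    }
    int rise = 0, fall = 0;
    for (int k = a; k <= ipk; ++k) if (up[k] >= thr) ++rise;
    for (int k = ipk + 1; k < b; ++k) if (up[k] >= thr) ++fall;
    out(c, 0) = pk; out(c, 1) = tr; out(c, 2) = open_n;
    out(c, 3) = rise; out(c, 4) = fall;
  }
  return out;
}
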