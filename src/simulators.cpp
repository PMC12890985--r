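#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Force field evaluation: either a polynomial gradient (dU coefficients in
// ascending powers) or linear interpolation on a grid.  Outside a grid the
// endpoint value is held (constant extrapolation).
struct ForceSpec {
  int type; // 0 = polynomial dU, 1 = gridded dU, 2 = zero
  NumericVector coef;   // dU polynomial coefficients, ascending
  NumericVector qg;     // grid positions (sorted)
  NumericVector fg;     // dU values on grid
  double dU(double q) const {
    if (type == 2) return 0.0;
    if (type == 0) {
      double s = 0.0;
      for (int i = coef.size() - 1; i >= 0; --i) s = s * q + coef[i];
      return s;
    }
    int n = qg.size();
    if (q <= qg[0]) return fg[0];
    if (q >= qg[n - 1]) return fg[n - 1];
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2; if (qg[mid] <= q) lo = mid; else hi = mid; }
    double w = (q - qg[lo]) / (qg[lo + 1] - qg[lo]);
    return fg[lo] * (1.0 - w) + fg[lo + 1] * w;
  }
};

static ForceSpec make_force(int pot_type, NumericVector dU_coef,
                            NumericVector qg, NumericVector fg) {
  ForceSpec f; f.type = pot_type; f.coef = dU_coef; f.qg = qg; f.fg = fg;
  return f;
}

// Linear interpolation with slope, for gamma(q) profiles.
struct Profile {
  NumericVector qg, g;
  // value and derivative at q (derivative 0 outside the grid)
  void eval(double q, double &val, double &slope) const {
    int n = qg.size();
    if (n == 1) { val = g[0]; slope = 0.0; return; }
    if (q <= qg[0]) { val = g[0]; slope = 0.0; return; }
    if (q >= qg[n - 1]) { val = g[n - 1]; slope = 0.0; return; }
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2; if (qg[mid] <= q) lo = mid; else hi = mid; }
    double h = qg[lo + 1] - qg[lo];
    slope = (g[lo + 1] - g[lo]) / h;
    val = g[lo] + slope * (q - qg[lo]);
  }
};

static inline void check_guard(double q, double qlo, double qhi, long step) {
  if (!(q > qlo && q < qhi) || !std::isfinite(q))
    stop("numerical blow-up: q = %f outside guard [%f, %f] at step %d",
         q, qlo, qhi, (int)step);
}

// GLE with multiexponential memory via auxiliary-particle Markovian embedding:
//   m dv = (-dU(q) - sum_i k_i (q - z_i)) dt,  dq = v dt,
//   dz_i = -(z_i - q)/tau_i dt + sqrt(2 kBT / gamma_i) dW_i,  k_i = gamma_i/tau_i.
// Splitting integrator: B(dt/2) A(dt/2) O(dt, exact OU on z at fixed q) A(dt/2) B(dt/2).
// [[Rcpp::export]]
List sim_gle_cpp(double m, double kBT, NumericVector gamma, NumericVector tau,
                 double dt, double q0, double v0, NumericVector z0,
                 long n_steps, int sub, long burn_steps,
                 int pot_type, NumericVector dU_coef,
                 NumericVector qgrid, NumericVector dUgrid,
                 double guard_lo, double guard_hi, bool record_v) {
  int nk = gamma.size();
  ForceSpec F = make_force(pot_type, dU_coef, qgrid, dUgrid);
  std::vector<double> k(nk), c1(nk), cs(nk), z(nk);
  for (int i = 0; i < nk; ++i) {
    k[i] = gamma[i] / tau[i];
    c1[i] = std::exp(-dt / tau[i]);
    cs[i] = std::sqrt(kBT / k[i] * (1.0 - c1[i] * c1[i]));
    z[i] = z0[i];
  }
  long n_rec = n_steps / sub;
  NumericVector qs(n_rec), vs(record_v ? n_rec : 0);
  double q = q0, v = v0;
  auto force = [&](double qq) {
    double f = -F.dU(qq);
    for (int i = 0; i < nk; ++i) f -= k[i] * (qq - z[i]);
    return f;
  };
  double f = force(q);
  long total = burn_steps + n_steps;
  long irec = 0;
  for (long s = 0; s < total; ++s) {
    v += 0.5 * dt / m * f;
    q += 0.5 * dt * v;
    for (int i = 0; i < nk; ++i)
      z[i] = q + (z[i] - q) * c1[i] + cs[i] * norm_rand();
    q += 0.5 * dt * v;
    f = force(q);
    v += 0.5 * dt / m * f;
    check_guard(q, guard_lo, guard_hi, s);
    if (s >= burn_steps && ((s - burn_steps + 1) % sub == 0) && irec < n_rec) {
      qs[irec] = q;
      if (record_v) vs[irec] = v;
      ++irec;
    }
  }
  List out = List::create(_["q"] = qs);
  if (record_v) out["v"] = vs;
  return out;
}

// Underdamped Langevin with constant friction (BAOAB).
// [[Rcpp::export]]
List sim_markovian_cpp(double m, double kBT, double gamma_tot,
                       double dt, double q0, double v0,
                       long n_steps, int sub, long burn_steps,
                       int pot_type, NumericVector dU_coef,
                       NumericVector qgrid, NumericVector dUgrid,
                       double guard_lo, double guard_hi, bool record_v) {
  ForceSpec F = make_force(pot_type, dU_coef, qgrid, dUgrid);
  double c1 = std::exp(-gamma_tot * dt / m);
  double cs = std::sqrt(kBT / m * (1.0 - c1 * c1));
  long n_rec = n_steps / sub;
  NumericVector qs(n_rec), vs(record_v ? n_rec : 0);
  double q = q0, v = v0, f = -F.dU(q);
  long total = burn_steps + n_steps, irec = 0;
  for (long s = 0; s < total; ++s) {
    v += 0.5 * dt / m * f;
    q += 0.5 * dt * v;
    v = c1 * v + cs * norm_rand();
    q += 0.5 * dt * v;
    f = -F.dU(q);
    v += 0.5 * dt / m * f;
    check_guard(q, guard_lo, guard_hi, s);
    if (s >= burn_steps && ((s - burn_steps + 1) % sub == 0) && irec < n_rec) {
      qs[irec] = q;
      if (record_v) vs[irec] = v;
      ++irec;
    }
  }
  List out = List::create(_["q"] = qs);
  if (record_v) out["v"] = vs;
  return out;
}

// Overdamped Langevin with coordinate-dependent friction, Ito form with the
// spurious-drift term that makes the stationary density exactly Boltzmann:
//   dq = [-dU/gamma - kBT gamma'/gamma^2] dt + sqrt(2 kBT/gamma) dW   (Ito)
// integrated with the Milstein correction for the multiplicative noise.
// [[Rcpp::export]]
NumericVector sim_qdep_over_cpp(double kBT, double dt, double q0,
                                long n_steps, int sub, long burn_steps,
                                int pot_type, NumericVector dU_coef,
                                NumericVector qgrid, NumericVector dUgrid,
                                NumericVector gq, NumericVector gv,
                                double guard_lo, double guard_hi) {
  ForceSpec F = make_force(pot_type, dU_coef, qgrid, dUgrid);
  Profile G; G.qg = gq; G.g = gv;
  long n_rec = n_steps / sub, irec = 0;
  NumericVector qs(n_rec);
  double q = q0, sqdt = std::sqrt(dt);
  long total = burn_steps + n_steps;
  for (long s = 0; s < total; ++s) {
    double g, gp;
    G.eval(q, g, gp);
    if (!(g > 0.0)) stop("gamma(q) <= 0 encountered at q = %f, step %d", q, (int)s);
    double sig = std::sqrt(2.0 * kBT / g);
    double sigp = -kBT * gp / (g * g) / sig; // d sigma / dq
    double drift = -F.dU(q) / g - kBT * gp / (g * g);
    double dW = sqdt * norm_rand();
    q += drift * dt + sig * dW + 0.5 * sig * sigp * (dW * dW - dt);
    check_guard(q, guard_lo, guard_hi, s);
    if (s >= burn_steps && ((s - burn_steps + 1) % sub == 0) && irec < n_rec)
      qs[irec++] = q;
  }
  return qs;
}

// Inertial Langevin with coordinate-dependent friction (BAOAB; the OU rate
// gamma(q)/m is evaluated at the mid-step position).  No spurious drift is
// needed: the noise amplitude depends on q only, so Boltzmann stationarity in
// (q, v) holds for the continuous-time equation.
// [[Rcpp::export]]
List sim_qdep_inertial_cpp(double m, double kBT, double dt, double q0, double v0,
                           long n_steps, int sub, long burn_steps,
                           int pot_type, NumericVector dU_coef,
                           NumericVector qgrid, NumericVector dUgrid,
                           NumericVector gq, NumericVector gv,
                           double guard_lo, double guard_hi, bool record_v) {
  ForceSpec F = make_force(pot_type, dU_coef, qgrid, dUgrid);
  Profile G; G.qg = gq; G.g = gv;
  long n_rec = n_steps / sub, irec = 0;
  NumericVector qs(n_rec), vs(record_v ? n_rec : 0);
  double q = q0, v = v0, f = -F.dU(q);
  long total = burn_steps + n_steps;
  for (long s = 0; s < total; ++s) {
    v += 0.5 * dt / m * f;
    q += 0.5 * dt * v;
    double g, gp;
    G.eval(q, g, gp);
    if (!(g > 0.0)) stop("gamma(q) <= 0 encountered at q = %f, step %d", q, (int)s);
    double c1 = std::exp(-g * dt / m);
    double cs = std::sqrt(kBT / m * (1.0 - c1 * c1));
    v = c1 * v + cs * norm_rand();
    q += 0.5 * dt * v;
    f = -F.dU(q);
    v += 0.5 * dt / m * f;
    check_guard(q, guard_lo, guard_hi, s);
    if (s >= burn_steps && ((s - burn_steps + 1) % sub == 0) && irec < n_rec) {
      qs[irec] = q;
      if (record_v) vs[irec] = v;
      ++irec;
    }
  }
  List out = List::create(_["q"] = qs);
  if (record_v) out["v"] = vs;
  return out;
}

// Time-origin-averaged MSD at the given integer lags, with standard errors
// from nb contiguous blocks of time origins.
// [[Rcpp::export]]
List msd_lags_cpp(NumericVector q, IntegerVector lags, int nb) {
  long n = q.size();
  int nl = lags.size();
  NumericVector msd(nl), se(nl);
  for (int il = 0; il < nl; ++il) {
    long k = lags[il];
    if (k == 0) { msd[il] = 0.0; se[il] = 0.0; continue; }
    long nor = n - k; // number of origins
    if (nor < 1) { msd[il] = NA_REAL; se[il] = NA_REAL; continue; }
    int nbl = (int)std::min((long)nb, nor);
    std::vector<double> bm(nbl, 0.0);
    std::vector<long> bc(nbl, 0);
    double tot = 0.0;
    for (long j = 0; j < nor; ++j) {
      double d = q[j + k] - q[j];
      double d2 = d * d;
      tot += d2;
      int b = (int)(j * (long)nbl / nor);
      bm[b] += d2; bc[b]++;
    }
    msd[il] = tot / nor;
    if (nbl > 1) {
      double mean = msd[il], ss = 0.0;
      int used = 0;
      for (int b = 0; b < nbl; ++b) if (bc[b] > 0) {
        double mb = bm[b] / bc[b];
        ss += (mb - mean) * (mb - mean);
        ++used;
      }
      se[il] = used > 1 ? std::sqrt(ss / (used - 1) / used) : NA_REAL;
    } else se[il] = NA_REAL;
  }
  return List::create(_["msd"] = msd, _["se"] = se);
}

// First-first-passage scan.  y = s*(q - qS) with s = +1/-1 the direction;
// targets u (>= 0, increasing) are distances |qF - qS| in the direction s.
// Renewal: on a crossing of 0 an event starts; the first subsequent arrival
// at each u_m is recorded (in samples); once the farthest target is reached
// the scan restarts at the current sample.  Crossing times of the start
// level and of each target are refined by linear interpolation between the
// straddling samples, which removes the O(Delta) discretization bias that
// would otherwise dominate nearby targets.
// [[Rcpp::export]]
List mfpt_scan_cpp(NumericVector y, NumericVector u) {
  long n = y.size();
  int M = u.size();
  NumericVector sum_t(M);
  IntegerVector cnt(M);
  long i = 1;
  bool in_event = false;
  double start = 0.0;
  int mi = 0;
  while (i < n) {
    if (!in_event) {
      if ((y[i - 1] <= 0.0 && y[i] >= 0.0) || (y[i - 1] >= 0.0 && y[i] <= 0.0)) {
        in_event = true;
        double dy = y[i] - y[i - 1];
        double frac = dy != 0.0 ? (0.0 - y[i - 1]) / dy : 0.0;
        start = (double)(i - 1) + frac;
        mi = 0;
        // register targets already passed within this sample interval
        while (mi < M && y[i] >= u[mi]) {
          double fr = dy != 0.0 ? (u[mi] - y[i - 1]) / dy : 1.0;
          if (fr < frac) fr = frac;
          sum_t[mi] += (double)(i - 1) + fr - start;
          cnt[mi]++; ++mi;
        }
        if (mi >= M) in_event = false;
      }
      ++i;
    } else {
      while (mi < M && y[i] >= u[mi]) {
        double dy = y[i] - y[i - 1];
        double fr = dy != 0.0 ? (u[mi] - y[i - 1]) / dy : 1.0;
        if (fr < 0.0) fr = 0.0;
        if (fr > 1.0) fr = 1.0;
        sum_t[mi] += (double)(i - 1) + fr - start;
        cnt[mi]++; ++mi;
      }
      if (mi >= M) { in_event = false; continue; } // rescan from this sample
      ++i;
    }
  }
  return List::create(_["sum"] = sum_t, _["count"] = cnt);
}

// Raw (uncentred) cross-correlation sum_j a[j] b[j+k] / (n-k) for k = 0..L.
// Direct O(n L) evaluation; used when FFT is not worthwhile.
// [[Rcpp::export]]
NumericVector cross_corr_direct_cpp(NumericVector a, NumericVector b, int L) {
  long n = a.size();
  NumericVector out(L + 1);
  for (int k = 0; k <= L; ++k) {
    double s = 0.0;
    long m = n - k;
    for (long j = 0; j < m; ++j) s += a[j] * b[j + k];
    out[k] = s / (double)m;
  }
  return out;
}

// Volterra forward substitution for the running friction integral G(t):
//   m (Cvv0 - Cvv_n) = Iuv_n + Delta * ( sum_{j=1}^{n-1} G_{n-j} Cvv_j
//                                        + 0.5 * G_n * Cvv_0 )
// (trapezoidal quadrature, G_0 = 0).
// [[Rcpp::export]]
NumericVector volterra_G_cpp(NumericVector cvv, NumericVector iuv,
                             double m, double delta) {
  int n = cvv.size();
  NumericVector G(n);
  double c0 = cvv[0];
  if (!(c0 > 0)) stop("Cvv(0) must be positive");
  G[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    double conv = 0.0;
    for (int j = 1; j < i; ++j) conv += G[i - j] * cvv[j];
    G[i] = (2.0 / (delta * c0)) * (m * (c0 - cvv[i]) - iuv[i] - delta * conv);
  }
  return G;
}
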