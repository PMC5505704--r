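#include <Rcpp.h>
using namespace Rcpp;

// Marko-Siggia interpolation force at extension x for contour length L,
// persistence length p, thermal energy kT. Optional enthalpic backbone
// correction (finite K rescales extension by (1 + F/K)) is handled at the
// R level via fixed-point iteration; kernels work on the pure form.
static inline double ms_force(double x, double L, double p, double kT) {
  double t = x / L;
  double u = 1.0 - t;
  return (kT / p) * (0.25 / (u * u) - 0.25 + t);
}

// [[Rcpp::export(name = ".wlc_force_cpp")]]
NumericVector wlc_force_cpp(NumericVector extension, double contour_length,
                            double persistence_length, double thermal_energy) {
  int n = extension.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = ms_force(extension[i], contour_length, persistence_length,
                      thermal_energy);
  return out;
}

// Inverse WLC: find Lc such that ms_force(x; Lc) = f, by bisection on
// Lc in (x * (1 + 1e-3/x), 10 x]. Force is strictly decreasing in Lc at
// fixed x, so the bracket is monotone. Points whose force is below
// `floor` (ill-conditioned) or outside the bracket return NA.
// [[Rcpp::export(name = ".wlc_inverse_cpp")]]
NumericVector wlc_inverse_cpp(NumericVector force, NumericVector extension,
                              double persistence_length, double thermal_energy,
                              double floor_pn, double rel_tol) {
  int n = force.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double f = force[i], x = extension[i];
    if (!R_finite(f) || !R_finite(x) || f < floor_pn || x <= 0.0) {
      out[i] = NA_REAL;
      continue;
    }
    double lo = x + 1e-3;   // Lc just above extension: very high force
    double hi = 10.0 * x;   // slack chain: low force
    double flo = ms_force(x, lo, persistence_length, thermal_energy);
    double fhi = ms_force(x, hi, persistence_length, thermal_energy);
    if (f > flo || f < fhi) {  // outside representable branch
      out[i] = NA_REAL;
      continue;
    }
    for (int it = 0; it < 200; ++it) {
      double mid = 0.5 * (lo + hi);
      double fm = ms_force(x, mid, persistence_length, thermal_energy);
      if (fm > f) lo = mid; else hi = mid;
      if ((hi - lo) <= rel_tol * hi) break;
    }
    out[i] = 0.5 * (lo + hi);
  }
  return out;
}

// Exact solution of the 1-D total variation proximal problem
//   min_x 0.5 * sum (y_i - x_i)^2 + lambda * sum |x_{i+1} - x_i|
// by Condat's direct (taut-string equivalent) algorithm, O(n) typical.
// [[Rcpp::export(name = ".tvd_condat_cpp")]]
NumericVector tvd_condat_cpp(NumericVector y, double lambda) {
  int n = y.size();
  NumericVector x(n);
  if (n == 0) return x;
  if (n == 1 || lambda <= 0.0) {
    for (int i = 0; i < n; ++i) x[i] = y[i];
    return x;
  }
  int k = 0, k0 = 0, km = 0, kp = 0;
  double vmin = y[0] - lambda, vmax = y[0] + lambda;
  double umin = lambda, umax = -lambda;
  while (true) {
    if (k == n - 1) {
      if (umin < 0.0) {            // negative jump needed
        do { x[k0++] = vmin; } while (k0 <= km);
        vmin = y[k0];
        umin = lambda;
        k = km = k0;
        umax = vmin + umin - vmax;
      } else if (umax > 0.0) {     // positive jump needed
        do { x[k0++] = vmax; } while (k0 <= kp);
        vmax = y[k0];
        umax = -lambda;
        k = kp = k0;
        umin = vmax + umax - vmin;
      } else {
        vmin += umin / (k - k0 + 1);
        for (int i = k0; i <= k; ++i) x[i] = vmin;
        return x;
      }
      if (k == n - 1 && k0 == n - 1) { x[k0] = vmin; return x; }
      if (k0 > n - 1) return x;
      continue;
    }
    double ynext = y[k + 1];
    if (ynext + umin < vmin - lambda) {          // break negative segment
      do { x[k0++] = vmin; } while (k0 <= km);
      k = km = kp = k0;
      vmin = y[k];
      vmax = y[k] + 2.0 * lambda;
      umin = lambda;
      umax = -lambda;
    } else if (ynext + umax > vmax + lambda) {   // break positive segment
      do { x[k0++] = vmax; } while (k0 <= kp);
      k = km = kp = k0;
      vmin = y[k] - 2.0 * lambda;
      vmax = y[k];
      umin = lambda;
      umax = -lambda;
    } else {
      ++k;
      umin += ynext - vmin;
      umax += ynext - vmax;
      if (umin >= lambda) {
        vmin += (umin - lambda) / (k - k0 + 1);
        umin = lambda;
        km = k;
      }
      if (umax <= -lambda) {
        vmax += (umax + lambda) / (k - k0 + 1);
        umax = -lambda;
        kp = k;
      }
    }
  }
}

// Solve the cantilever/WLC force balance k_c * d = F_wlc(z - d; Lc) for
// deflection d by bisection on d in [0, z).
static double solve_deflection(double z, double Lc, double kc, double p,
                               double kT) {
  if (z <= 0.0) return 0.0;
  double hi = std::min(z, 0.999999 * Lc / (1.0 + 1e-12));
  // extension x = z - d must stay below Lc; if z < Lc, d = 0 is feasible
  double lo = (z < Lc) ? 0.0 : (z - 0.999999 * Lc);
  double dhi = hi;
  for (int it = 0; it < 100; ++it) {
    double mid = 0.5 * (lo + dhi);
    double x = z - mid;
    double fw = (x > 0.0 && x < Lc) ? ms_force(x, Lc, p, kT) : (x >= Lc ? R_PosInf : 0.0);
    if (fw > kc * mid) lo = mid; else dhi = mid;
    if ((dhi - lo) < 1e-10 * (1.0 + dhi)) break;
  }
  return 0.5 * (lo + dhi);
}

// Constant-velocity pulling Monte Carlo. Transition parameters arrive as
// parallel vectors; `kinase[i]` marks transitions that fire in strict
// listed order (only the first unfired one is live); others are live from
// the start. `detach[i]` marks the curve-terminating transition.
// Uses R's RNG (seed via set.seed in R).
// [[Rcpp::export(name = ".simulate_pull_cpp")]]
List simulate_pull_cpp(NumericVector delta_contour, NumericVector k0,
                       NumericVector dx, LogicalVector kinase,
                       LogicalVector detach, double base_contour,
                       double speed, double spring_constant,
                       double sampling_rate, double noise_sd,
                       double persistence_length, double thermal_energy,
                       double max_pull) {
  RNGScope scope;
  int m = delta_contour.size();
  double dt = 1.0 / sampling_rate;
  int nmax = (int)std::ceil(max_pull / (speed * dt)) + 1;
  NumericVector zs(nmax), fs(nmax), fc(nmax);
  std::vector<int> ev_idx;
  std::vector<int> ev_which;
  std::vector<bool> fired(m, false);
  double Lc = base_contour;
  bool ended = false, truncated = false;
  int n = 0;
  for (int i = 0; i < nmax; ++i) {
    double z = speed * dt * i;
    double d = solve_deflection(z, Lc, spring_constant, persistence_length,
                                thermal_energy);
    double F = spring_constant * d;
    zs[i] = z;
    fc[i] = F;
    fs[i] = F + (noise_sd > 0.0 ? R::rnorm(0.0, noise_sd) : 0.0);
    n = i + 1;
    // determine live transitions and fire
    bool kin_seen_live = false;
    for (int j = 0; j < m; ++j) {
      if (fired[j]) continue;
      bool live;
      if (kinase[j]) {
        live = !kin_seen_live;
        kin_seen_live = true;
      } else {
        live = true;
      }
      if (!live) continue;
      double rate = k0[j] * std::exp(F * dx[j] / thermal_energy);
      double pfire = 1.0 - std::exp(-rate * dt);
      if (R::unif_rand() < pfire) {
        fired[j] = true;
        ev_idx.push_back(i + 1);       // 1-based sample index
        ev_which.push_back(j + 1);
        if (detach[j]) { ended = true; break; }
        Lc += delta_contour[j];
      }
    }
    if (ended) {
      // record a short zero-force tail (baseline) after detachment
      int tail = (int)std::ceil(30.0 / (speed * dt));  // 30 nm of travel
      for (int t2 = 1; t2 <= tail && (i + t2) < nmax; ++t2) {
        zs[i + t2] = speed * dt * (i + t2);
        fc[i + t2] = 0.0;
        fs[i + t2] = (noise_sd > 0.0 ? R::rnorm(0.0, noise_sd) : 0.0);
        n = i + t2 + 1;
      }
      break;
    }
  }
  if (!ended) truncated = true;
  return List::create(_["distance"] = NumericVector(zs.begin(), zs.begin() + n),
                      _["force"] = NumericVector(fs.begin(), fs.begin() + n),
                      _["force_clean"] = NumericVector(fc.begin(), fc.begin() + n),
                      _["event_index"] = IntegerVector(ev_idx.begin(), ev_idx.end()),
                      _["event_transition"] = IntegerVector(ev_which.begin(), ev_which.end()),
                      _["truncated"] = truncated);
}

// Best integer shift (in grid steps) of `a` against `b` minimizing the
// sum of squared differences over the overlap with zero padding.
// Returns the shift k (apply as: a moved right by k steps matches b).
// [[Rcpp::export(name = ".best_shift_cpp")]]
int best_shift_cpp(NumericVector a, NumericVector b, int max_shift) {
  int n = a.size();
  double best = R_PosInf;
  int bestk = 0;
  for (int k = -max_shift; k <= max_shift; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      int j = i - k;  // a shifted right by k: value at i is a[i - k]
      double av = (j >= 0 && j < n) ? a[j] : 0.0;
      double diff = av - b[i];
      s += diff * diff;
    }
    if (s < best - 1e-15) { best = s; bestk = k; }
  }
  return bestk;
}
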