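#include <Rcpp.h>
using namespace Rcpp;

// Per-timestep simulation of the coupled motor-cargo system.
//
// Units inside the kernel: positions um, forces pN, rates 1/s, time s.
// detach_family: 0 = never detach, 1 = Markovian (p1 = epsilon, p2 = F_d),
// 2 = non-Markovian (p1 = mu, p2 = tau_d, p3 = F_d).
// All Bernoulli thinning draws use R's RNG so a single set.seed() in R
// makes the whole trajectory reproducible.
// [[Rcpp::export]]
List simulate_kernel(int n_steps, double dt,
                     double l_um, double k_um, double beta,
                     double v0, double step_um, double f_stall,
                     int detach_family, double dp1, double dp2, double dp3,
                     double attach_rate, double backstep_prob,
                     NumericVector noise_x, NumericVector noise_y,
                     bool start_attached,
                     bool has_blocker, double blocker_x, double blocker_half) {
  NumericVector x(n_steps + 1), y(n_steps + 1), motor(n_steps + 1);
  IntegerVector att(n_steps + 1);
  double cx = 0.0, cy = 0.0, mx = 0.0, tau = 0.0;
  bool attached = start_attached;
  const double kmax = v0 / step_um;
  const double blo = blocker_x - blocker_half;
  const double bhi = blocker_x + blocker_half;
  if (has_blocker && attached && mx > blo && mx < bhi) mx = blo;

  x[0] = cx; y[0] = cy; att[0] = attached ? 1 : 0;
  motor[0] = attached ? mx : NA_REAL;

  for (int i = 0; i < n_steps; ++i) {
    double fx = 0.0, fy = 0.0, fmag = 0.0;
    if (attached) {
      const double dx = mx - cx, dy = -cy;
      const double dist = std::sqrt(dx * dx + dy * dy);
      if (dist > l_um) {
        // Hookean tether: force only when stretched beyond natural length
        fmag = k_um * (dist - l_um);
        fx = fmag * dx / dist;
        fy = fmag * dy / dist;
      }
      // force-dependent stepping (stalls at f_stall), 8-nm increments,
      // backward with probability backstep_prob
      double kappa = 0.0;
      if (fmag < f_stall) kappa = kmax * (1.0 - std::sqrt(fmag / f_stall));
      if (kappa > 0.0 && unif_rand() < kappa * dt) {
        const double step = (unif_rand() < backstep_prob) ? -step_um : step_um;
        const double nx = mx + step;
        bool blocked = false;
        if (has_blocker) {
          // the motor may neither occupy the blocker cross-section nor
          // step across it
          if ((nx > blo && nx < bhi) ||
              (mx <= blo && nx >= bhi) || (mx >= bhi && nx <= blo))
            blocked = true;
        }
        if (!blocked && nx >= 0.0) mx = nx;
      }
      // detachment hazard, thinned per step
      double rate = 0.0;
      if (detach_family == 1) rate = dp1 * std::exp(fmag / dp2);
      else if (detach_family == 2) rate = dp1 / (dp2 + tau) * std::exp(fmag / dp3);
      if (detach_family > 0 && unif_rand() < rate * dt) {
        attached = false;
      } else {
        tau += dt;
      }
    } else {
      if (attach_rate > 0.0 && unif_rand() < attach_rate * dt) {
        // reattach at the filament point nearest the cargo, outside any
        // blocker cross-section
        double px = cx < 0.0 ? 0.0 : cx;
        if (has_blocker && px >= blo && px <= bhi) {
          px = (cx < blocker_x) ? blo : bhi;
        }
        mx = px;
        attached = true;
        tau = 0.0;
      }
    }
    // explicit Euler update of the overdamped cargo
    cx += fx / beta * dt + noise_x[i];
    cy += fy / beta * dt + noise_y[i];
    if (!R_finite(cx) || !R_finite(cy))
      stop("non-finite cargo position at step %d", i + 1);
    x[i + 1] = cx;
    y[i + 1] = cy;
    att[i + 1] = attached ? 1 : 0;
    motor[i + 1] = attached ? mx : NA_REAL;
  }
  return List::create(_["x"] = x, _["y"] = y, _["attached"] = att,
                      _["motor_x"] = motor);
}

// First-passage scan: for each start index (spaced by `stride`), the first
// lag at which the displacement modulus reaches each threshold in ascending
// `thresholds`. Returns summed first-passage lags (in samples) and counts
// of contributing start points per threshold.
// [[Rcpp::export]]
List mfpt_kernel(NumericVector x, NumericVector y,
                 NumericVector thresholds, int stride) {
  const int n = x.size(), nl = thresholds.size();
  NumericVector total(nl);
  IntegerVector count(nl);
  for (int i = 0; i < n - 1; i += stride) {
    int li = 0;
    for (int j = i + 1; j < n && li < nl; ++j) {
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      const double r = std::sqrt(dx * dx + dy * dy);
      while (li < nl && r >= thresholds[li]) {
        total[li] += (double)(j - i);
        count[li] += 1;
        ++li;
      }
    }
  }
  return List::create(_["total"] = total, _["count"] = count);
}
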