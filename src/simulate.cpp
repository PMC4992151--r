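#include <Rcpp.h>
using namespace Rcpp;

// Fold a coordinate back into [0, H] (mirror reflection, possibly repeated
// when a single step overshoots both walls).
static inline double reflect(double y, double H) {
  while (y < 0.0 || y > H) {
    if (y < 0.0) y = -y; else y = 2.0 * H - y;
  }
  return y;
}

// Single-track jump-diffusion integrator.
//
// Each step the particle is either inside a ballistic jump (constant velocity
// L/tau_J along a fixed direction, Brownian component switched off) or
// diffusing.  A diffusing step draws one uniform number; if it falls in the
// centred interval of width p_jump a jump starts immediately (acceptance-
// rejection initiation), otherwise an isotropic Gaussian step with per-axis
// variance 2*D*dt is taken.  A new initiation is only tested after the running
// jump has completed.  Optional constant drift -v_sed acts on y every step;
// optional reflecting walls confine y to [0, H].
//
// Uses R's RNG (seed from R with set.seed before calling).
// [[Rcpp::export]]
List sim_track_cpp(double D, double p_jump, double L_T, double L_J,
                   double tau_J, double dt, int n_steps, int save_every,
                   bool instant_jumps, double v_sed, double H, bool walls,
                   bool record_state) {
  if (save_every < 1) stop("save_every must be >= 1");
  const int n_save = n_steps / save_every + 1;
  NumericVector xs(n_save), ys(n_save);
  IntegerVector st(record_state ? n_save : 0);
  std::vector<double> ev_start, ev_end, ev_len, ev_theta;

  double x = 0.0, y = 0.0;
  if (walls) y = unif_rand() * H;
  const double sigma = std::sqrt(2.0 * D * dt);
  const double lo = (1.0 - p_jump) / 2.0, hi = (1.0 + p_jump) / 2.0;
  const int n_jump_steps = (int)std::lround(tau_J / dt);
  int jump_left = 0;
  double ux = 0.0, uy = 0.0;

  xs[0] = x; ys[0] = y;
  if (record_state) st[0] = 0;
  int isave = 0;

  for (int i = 1; i <= n_steps; ++i) {
    int s = 0;
    if (jump_left > 0) {
      x += ux * dt; y += uy * dt;
      --jump_left; s = 1;
      if (jump_left == 0) ev_end.push_back(i * dt);
    } else {
      bool start = false;
      if (p_jump > 0.0) {
        const double u = unif_rand();
        start = (u >= lo && u <= hi);
      }
      if (start) {
        const double L = L_T + exp_rand() * L_J;
        const double th = unif_rand() * (2.0 * M_PI) - M_PI;
        ev_start.push_back((i - 1) * dt);
        ev_len.push_back(L);
        ev_theta.push_back(th);
        s = 1;
        if (instant_jumps) {
          x += L * std::cos(th); y += L * std::sin(th);
          ev_end.push_back(i * dt);
        } else {
          ux = (L / tau_J) * std::cos(th);
          uy = (L / tau_J) * std::sin(th);
          jump_left = n_jump_steps;
          x += ux * dt; y += uy * dt;
          --jump_left;
          if (jump_left == 0) ev_end.push_back(i * dt);
        }
      } else {
        x += sigma * norm_rand();
        y += sigma * norm_rand();
      }
    }
    y -= v_sed * dt;
    if (walls) y = reflect(y, H);
    if (i % save_every == 0) {
      ++isave;
      xs[isave] = x; ys[isave] = y;
      if (record_state) st[isave] = s;
    }
  }
  // track may end inside a jump: censor the event at the track end
  if (ev_end.size() < ev_start.size()) ev_end.push_back(n_steps * dt);

  return List::create(_["x"] = xs, _["y"] = ys, _["state"] = st,
                      _["t_start"] = ev_start, _["t_end"] = ev_end,
                      _["length"] = ev_len, _["theta"] = ev_theta);
}

// Sums of squared displacements at the requested integer lags for one track.
// [[Rcpp::export]]
List msd_accumulate_cpp(NumericVector x, NumericVector y, IntegerVector lags) {
  const int n = x.size(), m = lags.size();
  NumericVector acc(m);
  NumericVector npairs(m);
  for (int j = 0; j < m; ++j) {
    const int k = lags[j];
    if (k < 0 || k >= n) { acc[j] = 0.0; npairs[j] = 0.0; continue; }
    double s = 0.0;
    for (int i = 0; i + k < n; ++i) {
      const double dx = x[i + k] - x[i];
      const double dy = y[i + k] - y[i];
      s += dx * dx + dy * dy;
    }
    acc[j] = s;
    npairs[j] = n - k;
  }
  return List::create(_["sum_sq"] = acc, _["n_pairs"] = npairs);
}
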