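#include <Rcpp.h>
using namespace Rcpp;

static inline double wrap_pi(double a) {
  a -= 2.0 * M_PI * std::floor((a + M_PI) / (2.0 * M_PI));
  if (a <= -M_PI) a = M_PI;
  return a;
}

// Sensory evidence of one focal agent: signed clutter plus retinal motion
// slip with cos(bearing) gain. Mirrors the exported R reference functions
// perceived_clutter() / perceived_motion() / sensory_evidence().
// [[Rcpp::export]]
double evidence_cpp(NumericMatrix pos, NumericVector heading,
                    NumericMatrix vel, int focal, double fishsize,
                    double f_clutter, double w_clutter, double w_motion) {
  const int n = pos.nrow();
  const int j = focal - 1;  // R is 1-based
  double clutter = 0.0, motion = 0.0;
  const double hj = heading[j];
  for (int i = 0; i < n; ++i) {
    if (i == j) continue;
    double dx = pos(i, 0) - pos(j, 0);
    double dy = pos(i, 1) - pos(j, 1);
    double d = std::sqrt(dx * dx + dy * dy);
    if (d < 1.0) d = 1.0;
    double phi = wrap_pi(std::atan2(dy, dx) - hj);
    clutter += (phi < 0 ? 1.0 : -1.0) * 2.0 * std::atan(fishsize / (2.0 * d));
    double rvx = vel(i, 0) - vel(j, 0);
    double rvy = vel(i, 1) - vel(j, 1);
    double omega = (dx * rvy - dy * rvx) / (d * d);
    motion += -omega * std::cos(phi);
  }
  return w_clutter * f_clutter * clutter + w_motion * motion;
}

// Agent-based model of n_fish virtual fish in a circular arena, forward Euler
// at dt, trajectories exported every frame_dt. Bouts (20 px displacement and
// a heading change, N(0,5) deg forward / N(+/-22,25) deg turns, right
// positive) are executed through a first-order low-pass with time constant
// lp_tau; agents reaching the border get a fresh uniform orientation and are
// clamped inside.
// [[Rcpp::export]]
List collective_sim_cpp(int n_fish, double arena_d, double fishsize,
                        double dt, double duration, double frame_dt,
                        double tau, double sigma, double thresh,
                        double p_below, double p_above,
                        double f_clutter, double w_clutter, double w_motion,
                        double bout_dist, double lp_tau) {
  if (tau <= 0) stop("tau must be > 0");
  const double R_arena = arena_d / 2.0;
  const int n_steps = (int)std::lround(duration / dt);
  const int n_frames = (int)std::floor(duration / frame_dt + 1e-9) + 1;
  const double a = dt / tau;
  const double frac = dt / lp_tau;
  const double d2r = M_PI / 180.0;

  std::vector<double> px(n_fish), py(n_fish), h(n_fish), vx(n_fish, 0.0),
      vy(n_fish, 0.0), X(n_fish, 0.0), pend_d(n_fish, 0.0), pend_t(n_fish, 0.0);
  for (int i = 0; i < n_fish; ++i) {
    double r = 0.95 * R_arena * std::sqrt(R::unif_rand());
    double an = R::unif_rand() * 2.0 * M_PI - M_PI;
    px[i] = r * std::cos(an);
    py[i] = r * std::sin(an);
    h[i] = R::unif_rand() * 2.0 * M_PI - M_PI;
  }

  NumericMatrix fx(n_frames, n_fish), fy(n_frames, n_fish), fh(n_frames, n_fish);
  NumericVector ft(n_frames);
  std::vector<int> bout_fish, bout_turn;
  std::vector<double> bout_t, bout_dh;

  int frame = 0;
  for (int i = 0; i < n_fish; ++i) {
    fx(0, i) = px[i]; fy(0, i) = py[i]; fh(0, i) = h[i];
  }
  ft[0] = 0.0;
  frame = 1;

  std::vector<double> ev(n_fish), opx(n_fish), opy(n_fish);
  for (int s = 0; s < n_steps; ++s) {
    // evidence from the frozen pre-step state
    for (int j = 0; j < n_fish; ++j) {
      double clutter = 0.0, motion = 0.0;
      for (int i = 0; i < n_fish; ++i) {
        if (i == j) continue;
        double dx = px[i] - px[j], dy = py[i] - py[j];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < 1.0) d = 1.0;
        double phi = wrap_pi(std::atan2(dy, dx) - h[j]);
        clutter += (phi < 0 ? 1.0 : -1.0) * 2.0 * std::atan(fishsize / (2.0 * d));
        double omega = (dx * (vy[i] - vy[j]) - dy * (vx[i] - vx[j])) / (d * d);
        motion += -omega * std::cos(phi);
      }
      ev[j] = w_clutter * f_clutter * clutter + w_motion * motion;
    }
    for (int j = 0; j < n_fish; ++j) { opx[j] = px[j]; opy[j] = py[j]; }
    const double t_now = (s + 1) * dt;
    for (int j = 0; j < n_fish; ++j) {
      X[j] += (ev[j] - X[j] + R::rnorm(0.0, sigma)) * a;
      bool bout = false; double dh = 0.0; int is_turn = 0;
      if (std::fabs(X[j]) < thresh) {
        if (R::unif_rand() < p_below) {
          bout = true; dh = R::rnorm(0.0, 5.0); is_turn = 0;
        }
      } else if (R::unif_rand() < p_above) {
        bout = true; dh = R::rnorm(X[j] > 0 ? 22.0 : -22.0, 25.0); is_turn = 1;
      }
      if (bout) {
        pend_t[j] += -dh * d2r;       // right turns positive -> clockwise
        pend_d[j] += bout_dist;
        bout_fish.push_back(j); bout_t.push_back(t_now);
        bout_dh.push_back(dh); bout_turn.push_back(is_turn);
      }
      double dturn = pend_t[j] * frac;
      h[j] = wrap_pi(h[j] + dturn);
      pend_t[j] -= dturn;
      double dd = pend_d[j] * frac;
      px[j] += dd * std::cos(h[j]);
      py[j] += dd * std::sin(h[j]);
      pend_d[j] -= dd;
      double r = std::sqrt(px[j] * px[j] + py[j] * py[j]);
      if (r >= R_arena) {
        double scale = R_arena * (1.0 - 1e-9) / r;
        px[j] *= scale; py[j] *= scale;
        h[j] = R::unif_rand() * 2.0 * M_PI - M_PI;
        pend_d[j] = 0.0; pend_t[j] = 0.0;
      }
      vx[j] = (px[j] - opx[j]) / dt;
      vy[j] = (py[j] - opy[j]) / dt;
    }
    if (frame < n_frames && t_now + 1e-9 >= frame * frame_dt) {
      for (int i = 0; i < n_fish; ++i) {
        fx(frame, i) = px[i]; fy(frame, i) = py[i]; fh(frame, i) = h[i];
      }
      ft[frame] = t_now;
      ++frame;
    }
  }
  if (frame < n_frames) {  // trim (should not happen)
    ft = ft[Range(0, frame - 1)];
    fx = fx(Range(0, frame - 1), _);
    fy = fy(Range(0, frame - 1), _);
    fh = fh(Range(0, frame - 1), _);
  }
  return List::create(_["t"] = ft, _["x"] = fx, _["y"] = fy, _["heading"] = fh,
                      _["bout_fish"] = wrap(bout_fish),
                      _["bout_t"] = wrap(bout_t),
                      _["bout_dh"] = wrap(bout_dh),
                      _["bout_is_turn"] = wrap(bout_turn));
}
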