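#include <Rcpp.h>
using namespace Rcpp;

// Euler simulation of the leaky drift-diffusion bout model.
// drive: signed per-step stimulus (coherence fraction * direction).
// Returns one row per emitted bout: fish (0-based), step (0-based),
// dheading_deg (right turns positive), is_turn (threshold state at emission).
// [[Rcpp::export]]
List ddm_sim_cpp(double tau, double sigma, double thresh,
                 double p_below, double p_above,
                 NumericVector drive, double dt, int n_fish) {
  if (tau <= 0) stop("tau must be > 0");
  const int n_steps = drive.size();
  std::vector<int> fish, step;
  std::vector<double> dh;
  std::vector<int> turn;
  const double a = dt / tau;
  for (int f = 0; f < n_fish; ++f) {
    double X = 0.0;
    for (int s = 0; s < n_steps; ++s) {
      X += (drive[s] - X + R::rnorm(0.0, sigma)) * a;
      if (std::fabs(X) < thresh) {
        if (R::unif_rand() < p_below) {
          fish.push_back(f); step.push_back(s);
          dh.push_back(R::rnorm(0.0, 5.0));
          turn.push_back(0);
        }
      } else if (R::unif_rand() < p_above) {
        fish.push_back(f); step.push_back(s);
        dh.push_back(R::rnorm(X > 0 ? 22.0 : -22.0, 25.0));
        turn.push_back(1);
      }
    }
  }
  return List::create(_["fish"] = wrap(fish), _["step"] = wrap(step),
                      _["dheading_deg"] = wrap(dh), _["is_turn"] = wrap(turn));
}
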