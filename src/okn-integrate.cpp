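#include <Rcpp.h>
using namespace Rcpp;

// Sequential sawtooth OKN integrator. Slow phases drift opposite to the
// fast-phase direction at a state-dependent velocity; a fast phase is
// triggered when eccentricity reaches reset_ecc on the drift side, with a
// gamma-distributed, state-dependent duration at fixed fast-phase speed
// (so fast-phase extent is state-dependent too). Uses R's RNG so results
// are reproducible under set.seed().
//
// state: 1 = integrated, 2 = segregated, per sample.
// Returns position (deg) and a phase code per sample (0 slow, 1 fast).
// [[Rcpp::export]]
List okn_integrate(IntegerVector state, double rate, double v_int,
                   double v_seg, double fast_dir, double reset_ecc,
                   double dur_int_ms, double dur_seg_ms, double dur_cv,
                   double fast_speed, double noise_sd, double start_pos) {
  int n = state.size();
  NumericVector x(n);
  IntegerVector phase(n);
  double dt = 1.0 / rate;
  double pos = start_pos;
  int fast_left = 0;
  double shp = (dur_cv > 0) ? 1.0 / (dur_cv * dur_cv) : 0.0;
  for (int i = 0; i < n; ++i) {
    bool seg = state[i] == 2;
    if (fast_left > 0) {
      pos += fast_dir * fast_speed * dt;
      --fast_left;
      phase[i] = 1;
    } else {
      pos += -fast_dir * (seg ? v_seg : v_int) * dt;
      phase[i] = 0;
      if (std::abs(pos) >= reset_ecc && pos * fast_dir < 0) {
        double mdur = seg ? dur_seg_ms : dur_int_ms;
        double d = (shp > 0) ? R::rgamma(shp, mdur / shp) : mdur;
        int k = (int)std::lround(d * rate / 1000.0);
        fast_left = k < 3 ? 3 : k;
      }
    }
    x[i] = pos + (noise_sd > 0 ? R::rnorm(0.0, noise_sd) : 0.0);
  }
  return List::create(_["x"] = x, _["phase"] = phase);
}
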