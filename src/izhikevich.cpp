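#include <Rcpp.h>
using namespace Rcpp;

// Advance a population of Izhikevich units over `substeps` forward-Euler
// substeps of dt ms under a constant input current I (same for every unit).
// v is advanced in two half-steps of dt/2 per substep; u once per substep
// using the updated v. A unit entering a substep at or above the 30 mV
// threshold is reset (v <- c, u <- u + d) and does not integrate that
// substep, so post-spike state is exact. Dynamics are fully deterministic:
// all randomness lives in the per-unit parameters drawn at trial reset.
//
// [[Rcpp::export]]
List izhi_population_steps(NumericVector v, NumericVector u,
                           NumericVector a, NumericVector b,
                           NumericVector c, NumericVector d,
                           double I, int substeps, double dt) {
  int n = v.size();
  NumericVector vv = clone(v), uu = clone(u);
  int spikes = 0;
  for (int s = 0; s < substeps; ++s) {
    for (int i = 0; i < n; ++i) {
      double vi = vv[i], ui = uu[i];
      if (vi >= 30.0) {
        vv[i] = c[i];
        uu[i] = ui + d[i];
        ++spikes;
        continue;
      }
      vi = vi + 0.5 * dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I);
      vi = vi + 0.5 * dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I);
      ui = ui + dt * a[i] * (b[i] * vi - ui);
      if (vi >= 30.0) {
        vi = c[i];
        ui = ui + d[i];
        ++spikes;
      }
      vv[i] = vi;
      uu[i] = ui;
    }
  }
  return List::create(_["v"] = vv, _["u"] = uu, _["spikes"] = spikes);
}
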