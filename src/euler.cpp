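#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step explicit Euler integration of the three-compartment phosphate
// system with the mid-treatment-centred linear clearance-reduction factor.
//
// State is carried as compartment masses (mmol) so that the cumulative
// removal accumulated on the same grid conserves total mass exactly at
// machine precision. The dialysate-side concentration profile, when given,
// is evaluated stepwise-constant (last observation carried forward, zero
// before the first sample); an empty profile means Cd(t) = 0.
//
// The dialysis status gate is closed-open: s = 1 for t in [t0, t0 + Dd),
// s = 0 at the final grid point.
// [[Rcpp::export]]
List euler_core(double c0, double V1, double V2, double V3,
                double kd, double k1, double k2, double slc,
                double dd_h, double t0_h, double step_h,
                NumericVector cd_times_h, NumericVector cd_values) {
  int n_steps = (int) std::lround(dd_h / step_h);
  if (n_steps < 1) stop("session shorter than one integration step");
  int n = n_steps + 1;
  NumericVector times(n), C1(n), C2(n), C3(n), F1(n), removed(n);
  double M1 = c0 * V1, M2 = c0 * V2, M3 = c0 * V3, rem = 0.0;
  int ncd = cd_times_h.size();
  for (int i = 0; i < n; ++i) {
    double t = t0_h + i * step_h;
    double c1 = V1 > 0 ? M1 / V1 : 0.0;
    double c2 = V2 > 0 ? M2 / V2 : 0.0;
    double c3 = V3 > 0 ? M3 / V3 : 0.0;
    double cd = 0.0;
    for (int j = ncd - 1; j >= 0; --j) {
      if (t >= cd_times_h[j] - 1e-12) { cd = cd_values[j]; break; }
    }
    double s = (i < n_steps) ? 1.0 : 0.0;
    double raw = slc * ((t - t0_h) - dd_h / 2.0);
    double adj = (raw > 1.0) ? 0.0 : 1.0 - raw;
    double f1 = kd * (c1 - cd) * adj * s;
    times[i] = t; C1[i] = c1; C2[i] = c2; C3[i] = c3; F1[i] = f1;
    removed[i] = rem;
    if (i < n_steps) {
      double f2 = k1 * (c2 - c1);   // compartment 2 -> 1
      double f3 = k2 * (c3 - c2);   // compartment 3 -> 2
      M1 += step_h * (f2 - f1);
      M2 += step_h * (f3 - f2);
      M3 += step_h * (-f3);
      rem += step_h * f1;
      if (M1 < 0.0 || M2 < 0.0 || M3 < 0.0)
        stop("negative compartment mass at t = %.4f h; use a smaller integration step",
             t + step_h);
    }
  }
  return List::create(_["time_h"] = times, _["c1"] = C1, _["c2"] = C2,
                      _["c3"] = C3, _["f1_mmol_h"] = F1,
                      _["removed_mmol"] = removed);
}
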