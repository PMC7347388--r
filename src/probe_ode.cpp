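#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integration of the probe equation of motion
//   m x'' + c x' + k x = F(t)
// with t in ms, x in um, F in uN, m in mg, c in mg/ms, k in uN/um
// (these units are mutually consistent: 1 mg*um/ms^2 = 1 uN).
// The force is sampled on a uniform grid with spacing dt_in (ms) and linearly
// interpolated between samples; the solution is recorded at the input grid.
// [[Rcpp::export(name = ".probe_rk4")]]
NumericVector probe_rk4(NumericVector force, double dt_in,
                        double k, double m, double c,
                        double x0, double v0, double h) {
  const int n = force.size();
  NumericVector x_out(n);
  if (n == 0) return x_out;
  const int nsub = std::max(1, (int)std::ceil(dt_in / h - 1e-9));
  const double hs = dt_in / nsub; // exact substep so grid points are hit
  double x = x0, v = v0;
  x_out[0] = x0;
  for (int i = 0; i < n - 1; ++i) {
    const double f0 = force[i], f1 = force[i + 1];
    for (int s = 0; s < nsub; ++s) {
      // force linearly interpolated at substep times
      const double t0 = (double)s / nsub, tm = (s + 0.5) / nsub,
                   t1 = (double)(s + 1) / nsub;
      const double F0 = f0 + (f1 - f0) * t0;
      const double Fm = f0 + (f1 - f0) * tm;
      const double F1 = f0 + (f1 - f0) * t1;
      const double k1x = v;
      const double k1v = (F0 - c * v - k * x) / m;
      const double k2x = v + 0.5 * hs * k1v;
      const double k2v = (Fm - c * (v + 0.5 * hs * k1v) - k * (x + 0.5 * hs * k1x)) / m;
      const double k3x = v + 0.5 * hs * k2v;
      const double k3v = (Fm - c * (v + 0.5 * hs * k2v) - k * (x + 0.5 * hs * k2x)) / m;
      const double k4x = v + hs * k3v;
      const double k4v = (F1 - c * (v + hs * k3v) - k * (x + hs * k3x)) / m;
      x += hs / 6.0 * (k1x + 2 * k2x + 2 * k3x + k4x);
      v += hs / 6.0 * (k1v + 2 * k2v + 2 * k3v + k4v);
    }
    x_out[i + 1] = x;
  }
  return x_out;
}
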