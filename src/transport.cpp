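#include <Rcpp.h>
using namespace Rcpp;

// Drift-diffusion time stepping of charge carriers in a uniform field,
// compiled because the per-carrier random walk is the innermost loop of
// the simulation (tens of millions of carriers per study).
//
// Carriers drift along +/- y with a constant speed (uniform field) and
// receive independent Gaussian diffusion kicks of standard deviation
// sigma_step = sqrt(2 D dt) in x and in y each step.  A carrier is
// collected when its y coordinate crosses its collection boundary
// (y = 0 for holes, y = thickness for electrons); the final partial step
// is linearly interpolated onto the boundary.  The lateral walls
// reflect.  Randomness comes from R's normal generator, so results are
// reproducible under set.seed().

// [[Rcpp::export(name = ".cc_transport_endpoints")]]
NumericMatrix cc_transport_endpoints(NumericVector x0, NumericVector y0,
                                     double drift_step_um, int direction,
                                     double sigma_step_um, double dt,
                                     double thickness, double x_halfwidth,
                                     int max_steps) {
  const int n = x0.size();
  NumericMatrix out(n, 2); // end x, collection time
  const double drift = direction * drift_step_um;
  for (int i = 0; i < n; ++i) {
    double x = x0[i], y = y0[i];
    double t = 0.0;
    int steps = 0;
    // Carriers created exactly on their collection boundary are
    // collected immediately.
    for (;;) {
      if (direction < 0 && y <= 0.0) break;
      if (direction > 0 && y >= thickness) break;
      if (++steps > max_steps)
        stop("carrier exceeded max_steps without collection (physics/config bug)");
      double xn = x + sigma_step_um * norm_rand();
      double yn = y + drift + sigma_step_um * norm_rand();
      double ycross = (direction < 0) ? 0.0 : thickness;
      bool crossed = (direction < 0) ? (yn <= ycross) : (yn >= ycross);
      if (crossed) {
        double frac = (y - ycross) / (y - yn);
        x = x + frac * (xn - x);
        y = ycross;
        t += frac * dt;
      } else {
        // A diffusion kick can also push a carrier across the opposite
        // plane; clamp it there (it will drift back next step).
        if (yn < 0.0) yn = 0.0;
        if (yn > thickness) yn = thickness;
        x = xn;
        y = yn;
        t += dt;
      }
      // reflecting side walls
      if (x < -x_halfwidth) x = -2.0 * x_halfwidth - x;
      if (x > x_halfwidth) x = 2.0 * x_halfwidth - x;
      if (crossed) break;
    }
    out(i, 0) = x;
    out(i, 1) = t;
  }
  return out;
}
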