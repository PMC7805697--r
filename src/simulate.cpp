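#include <Rcpp.h>
using namespace Rcpp;

// Wrap an angle difference into (-pi, pi].
static inline double wrap_angle(double a) {
  return std::atan2(std::sin(a), std::cos(a));
}

// Burst-and-coast random walker confined to an axis-aligned box.
//
// Bursts arrive as a Poisson process (per-step probability 1 - exp(-rate*dt)).
// At a burst the speed resets to a truncated-Gaussian draw and the heading
// receives a Gaussian increment whose mean is the wrapped bearing error to the
// attraction point scaled by attraction_gain (plus an analogous lateral-bias
// term pulling toward the y = side_y wall).  Between bursts the speed decays
// exponentially with time constant coast_decay_time.  Within wall_range of a
// wall extra heading jitter is applied; boundary crossings are handled by
// specular reflection of position and heading.
//
// Uses R's RNG so results are reproducible from set.seed().
// [[Rcpp::export]]
List bc_simulate_cpp(int n_steps, double dt,
                     double x0, double y0, double heading0, double speed0,
                     double burst_rate, double burst_speed_mean,
                     double burst_speed_sd, double coast_decay_time,
                     double turn_sd,
                     double attraction_gain, double att_x, double att_y,
                     bool has_attraction,
                     double side_bias, double side_y,
                     double wall_range, double wall_noise_sd,
                     double xmin, double xmax, double ymin, double ymax) {
  NumericVector x(n_steps + 1), y(n_steps + 1), spd(n_steps + 1),
      hdg(n_steps + 1);
  LogicalVector burst(n_steps + 1);
  double px = x0, py = y0, h = heading0, s = speed0;
  const double p_burst = 1.0 - std::exp(-burst_rate * dt);
  const double decay = std::exp(-dt / coast_decay_time);
  x[0] = px; y[0] = py; spd[0] = s; hdg[0] = h; burst[0] = false;
  for (int i = 1; i <= n_steps; i++) {
    const bool b = (unif_rand() < p_burst);
    if (b) {
      double mu = 0.0;
      if (has_attraction && attraction_gain != 0.0) {
        double bearing = std::atan2(att_y - py, att_x - px);
        mu += attraction_gain * wrap_angle(bearing - h);
      }
      if (side_bias != 0.0) {
        double bearing = (side_y >= py) ? M_PI_2 : -M_PI_2;
        mu += side_bias * wrap_angle(bearing - h);
      }
      h += mu + norm_rand() * turn_sd;
      s = burst_speed_mean + norm_rand() * burst_speed_sd;
      if (s < 0.0) s = 0.0;
    } else {
      s *= decay;
    }
    const double dwall = std::min(std::min(px - xmin, xmax - px),
                                  std::min(py - ymin, ymax - py));
    if (dwall < wall_range && wall_noise_sd > 0.0)
      h += norm_rand() * wall_noise_sd;
    double nx = px + s * dt * std::cos(h);
    double ny = py + s * dt * std::sin(h);
    double vx = std::cos(h), vy = std::sin(h);
    bool reflected = false;
    for (int k = 0; k < 8; k++) {  // corner cases may need both axes
      bool r = false;
      if (nx < xmin)      { nx = 2 * xmin - nx; vx = -vx; r = true; }
      else if (nx > xmax) { nx = 2 * xmax - nx; vx = -vx; r = true; }
      if (ny < ymin)      { ny = 2 * ymin - ny; vy = -vy; r = true; }
      else if (ny > ymax) { ny = 2 * ymax - ny; vy = -vy; r = true; }
      reflected = reflected || r;
      if (!r) break;
    }
    if (nx < xmin) nx = xmin; else if (nx > xmax) nx = xmax;
    if (ny < ymin) ny = ymin; else if (ny > ymax) ny = ymax;
    if (reflected) h = std::atan2(vy, vx);
    px = nx; py = ny;
    x[i] = px; y[i] = py; spd[i] = s; hdg[i] = h; burst[i] = b;
  }
  return List::create(_["x"] = x, _["y"] = y, _["speed"] = spd,
                      _["heading"] = hdg, _["burst"] = burst);
}
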