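#' Burst-and-coast swimming parameters
#'
#' Parameters of the stochastic locomotion model.  Zebrafish swim in a
#' burst-and-coast style: sudden tail beats (bursts) reset the speed and turn
#' the heading, and are followed by longer passive coasting phases during
#' which speed decays exponentially.  Defaults give realistic speeds of a few
#' body lengths per second at the 20 Hz tracking rate.
#'
#' @param burst_rate Poisson rate of burst events (events/s); must be > 0.
#' @param burst_speed_mean,burst_speed_sd Post-burst speed draw (cm/s);
#'   negative draws are clipped to 0.
#' @param coast_decay_time Exponential speed-decay time constant (s).
#' @param turn_sd Standard deviation of the Gaussian heading increment per
#'   burst (rad).
#' @param attraction_gain In `[0, 1]`; at each burst the mean heading
#'   increment is the bearing error toward the attraction point scaled by
#'   this gain.  0 gives an unbiased walker.
#' @param wall_repulsion_range Distance (cm) from a wall within which extra
#'   heading randomization is applied (prevents boundary sticking).
#' @param wall_noise_sd SD (rad) of the per-step wall heading jitter.
#' @param dt Sampling step (s); default 1/20 s, the tracking frame interval.
#' @return A `bc_swim_params` list.
#' @export
swim_params <- function(burst_rate = 1, burst_speed_mean = 10,
                        burst_speed_sd = 3, coast_decay_time = 0.4,
                        turn_sd = 0.6, attraction_gain = 0,
                        wall_repulsion_range = 3, wall_noise_sd = 0.3,
                        dt = 0.05) {
  if (burst_rate <= 0) stop("burst_rate must be positive")
  if (coast_decay_time <= 0) stop("coast_decay_time must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (burst_speed_mean < 0 || burst_speed_sd < 0)
    stop("burst speed parameters must be non-negative")
  if (attraction_gain < 0 || attraction_gain > 1)
    stop("attraction_gain must lie in [0, 1]")
  structure(list(burst_rate = burst_rate,
                 burst_speed_mean = burst_speed_mean,
                 burst_speed_sd = burst_speed_sd,
                 coast_decay_time = coast_decay_time,
                 turn_sd = turn_sd, attraction_gain = attraction_gain,
                 wall_repulsion_range = wall_repulsion_range,
                 wall_noise_sd = wall_noise_sd, dt = dt),
            class = "bc_swim_params")
}

#' Trajectory container
#'
#' A trajectory is a data frame with columns `t_s`, `x_cm`, `y_cm`,
#' `identity`, `valid`, `interpolated` on a strictly increasing uniform time
#' grid, plus attributes `dt` (s).  This is also the on-disk CSV dialect
#' (see [write_trajectory_csv()]).
#'
#' @param t,x,y Numeric vectors of equal length (s, cm, cm).
#' @param identity `"subject"` or `"replica"`.
#' @param valid,interpolated Logical flags per sample; `interpolated` marks
#'   samples estimated by the Kalman predictor rather than detected.
#' @param dt Grid step (s); defaults to the median time difference.
#' @return A `bc_trajectory` data frame.
#' @export
new_trajectory <- function(t, x, y, identity = "subject",
                           valid = TRUE, interpolated = FALSE, dt = NULL) {
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n, n >= 1)
  if (is.null(dt)) dt <- if (n > 1) median(diff(t)) else NA_real_
  traj <- data.frame(t_s = t, x_cm = x, y_cm = y,
                     identity = rep_len(identity, n),
                     valid = rep_len(valid, n),
                     interpolated = rep_len(interpolated, n))
  structure(traj, dt = dt, class = c("bc_trajectory", "data.frame"))
}

traj_dt <- function(traj) {
  dt <- attr(traj, "dt")
  if (is.null(dt) || is.na(dt)) dt <- median(diff(traj$t_s))
  dt
}

#' Simulate one burst-and-coast trajectory
#'
#' Runs the stochastic locomotion model inside an axis-aligned region of the
#' tank (by default the whole tank).  Burst events arrive as a Poisson
#' process; at each burst the speed resets to a Gaussian draw and the heading
#' receives a Gaussian increment whose mean is rotated toward the attraction
#' point in proportion to `attraction_gain`.  Between bursts the speed decays
#' exponentially.  Walls reflect the fish specularly with a small heading
#' randomization within `wall_repulsion_range`.
#'
#' @param params A [swim_params()] object.
#' @param arena A `bc_arena`.
#' @param duration Duration (s); samples are produced at `t = 0, dt, ...,
#'   duration` (i.e. `duration/dt + 1` samples).
#' @param start Starting position `c(x, y)` (cm), inside `bounds`.
#' @param attraction_point Optional `c(x, y)` attraction target.
#' @param side_bias Gain (>= 0) of a constant lateral attraction toward the
#'   `side_y` wall, emulating an uncontrolled environmental side bias.
#' @param side_y y coordinate of the preferred side wall (default 0).
#' @param bounds Optional confinement `c(xmin, xmax, ymin, ymax)`; defaults
#'   to the full tank.  Use [compartment_zone()] bounds to confine the
#'   subject to the focal compartment during the release phase.
#' @param initial_speed,initial_heading Initial state; heading defaults to a
#'   uniform random angle.
#' @param seed Optional integer seed (calls [set.seed()]); identical seeds
#'   give bit-identical trajectories.
#' @param identity Identity label for the trajectory.
#' @return A `bc_trajectory` with extra attributes `speed`, `heading`,
#'   `burst` (per-sample model state, used by diagnostics and tests).
#' @examples
#' arena <- make_default_arena()
#' tr <- simulate_trajectory(swim_params(), arena, duration = 10,
#'                           start = c(15, 15), seed = 1)
#' range(tr$x_cm)
#' @export
simulate_trajectory <- function(params, arena, duration, start,
                                attraction_point = NULL, side_bias = 0,
                                side_y = 0, bounds = NULL,
                                initial_speed = 0, initial_heading = NULL,
                                seed = NULL, identity = "subject") {
  stopifnot(inherits(params, "bc_swim_params"))
  if (duration <= 0) stop("duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(bounds)) bounds <- c(0, arena$length, 0, arena$width)
  if (start[1] < bounds[1] || start[1] > bounds[2] ||
      start[2] < bounds[3] || start[2] > bounds[4])
    stop("start position outside the simulation bounds")
  if (is.null(initial_heading)) initial_heading <- runif(1, -pi, pi)
  n_steps <- round(duration / params$dt)
  has_att <- !is.null(attraction_point)
  att <- if (has_att) attraction_point else c(0, 0)
  sim <- bc_simulate_cpp(
    n_steps, params$dt, start[1], start[2], initial_heading, initial_speed,
    params$burst_rate, params$burst_speed_mean, params$burst_speed_sd,
    params$coast_decay_time, params$turn_sd,
    params$attraction_gain, att[1], att[2], has_att,
    side_bias, side_y,
    params$wall_repulsion_range, params$wall_noise_sd,
    bounds[1], bounds[2], bounds[3], bounds[4])
  traj <- new_trajectory(t = seq(0, by = params$dt, length.out = n_steps + 1),
                         x = sim$x, y = sim$y, identity = identity,
                         dt = params$dt)
  attr(traj, "speed") <- sim$speed
  attr(traj, "heading") <- sim$heading
  attr(traj, "burst") <- sim$burst
  traj
}
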