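#' Metric computation options
#'
#' @param entropy_grid Bins per axis of the occupancy grid over the focal
#'   compartment (default 10, i.e. 100 bins, the summation limit of the
#'   entropy formula).
#' @param speed_floor Minimum displacement speed (cm/s) for heading-error
#'   and turn-rate samples; avoids arccos of near-zero vectors.
#' @param freezing_mode `"net"` (net displacement between the endpoints of
#'   the rolling window; the strict reading of "moved < 4 cm") or `"path"`
#'   (cumulative path length within the window).
#' @param freezing_window Rolling-window length (s); default 2.
#' @param freezing_threshold Displacement threshold (cm); default 4.
#' @param avoidance_window Post-opening observation window (s); default 15.
#' @param truncate_at_open If TRUE (default), all measures are computed on
#'   the release phase up to door opening (or the full limit if censored).
#' @return A `bc_metric_options` list.
#' @export
metric_options <- function(entropy_grid = 10, speed_floor = 0.5,
                           freezing_mode = c("net", "path"),
                           freezing_window = 2, freezing_threshold = 4,
                           avoidance_window = 15, truncate_at_open = TRUE) {
  freezing_mode <- match.arg(freezing_mode)
  structure(list(entropy_grid = entropy_grid, speed_floor = speed_floor,
                 freezing_mode = freezing_mode,
                 freezing_window = freezing_window,
                 freezing_threshold = freezing_threshold,
                 avoidance_window = avoidance_window,
                 truncate_at_open = truncate_at_open),
            class = "bc_metric_options")
}

# Samples of the release phase up to door opening (or the censoring limit).
scored_window <- function(trial, opts) {
  traj <- trial$trajectory
  if (opts$truncate_at_open && !is.null(trial$T) && !is.na(trial$T) &&
      isFALSE(trial$censored)) {
    traj[traj$t_s <= trial$T + 1e-9, , drop = FALSE]
  } else traj
}

#' Door-proximity times and preference index
#'
#' `tau_C` / `tau_I` are the times spent in the 6 x 6 cm trigger zones in
#' front of the correct / incorrect door (sample count x dt, valid samples,
#' release phase up to door opening).  The preference index is
#' `PI = tau_C / (tau_C + tau_I)`, `NA` (no preference measurable) when the
#' subject never visited either zone.
#'
#' @param trial A `bc_trial` (after [run_trial_session()]).
#' @param arena A `bc_arena`.
#' @param opts A [metric_options()].
#' @return List with `tau_C`, `tau_I` (s), and `PI`.
#' @export
door_time_metrics <- function(trial, arena, opts = metric_options()) {
  traj <- scored_window(trial, opts)
  dt <- traj_dt(trial$trajectory)
  pos <- cbind(traj$x_cm, traj$y_cm)
  ok <- traj$valid
  incorrect <- setdiff(c("lower", "upper"), trial$correct_door)
  in_c <- zone_contains(trigger_zone(arena, trial$correct_door), pos) & ok
  in_i <- zone_contains(trigger_zone(arena, incorrect), pos) & ok
  tau_C <- sum(in_c) * dt
  tau_I <- sum(in_i) * dt
  list(tau_C = tau_C, tau_I = tau_I,
       PI = if (tau_C + tau_I > 0) tau_C / (tau_C + tau_I) else NA_real_)
}

#' Wall-proximity times and reward index
#'
#' Each valid sample within `arena$wall_band` (3 cm) of at least one
#' focal-compartment wall is assigned to the nearest such wall.  Wall 1 is
#' the door partition, nearest the conspecific shoal, so the reward index
#' `RI = T_wall1 / sum(T_wall)` quantifies preference for swimming close to
#' conspecifics; it is `NA` if the subject never entered any wall band.
#'
#' @inheritParams door_time_metrics
#' @return List with `T_wall` (length 4, s) and `RI`.
#' @export
wall_metrics <- function(trial, arena, opts = metric_options()) {
  traj <- scored_window(trial, opts)
  dt <- traj_dt(trial$trajectory)
  ok <- traj$valid
  nw <- nearest_wall(arena, cbind(pmin(traj$x_cm, arena$focal_len),
                                  traj$y_cm))
  in_band <- nw$distance <= arena$wall_band & ok
  T_wall <- vapply(1:4, function(w) sum(in_band & nw$wall == w) * dt, 0)
  tot <- sum(T_wall)
  list(T_wall = T_wall, RI = if (tot > 0) T_wall[1] / tot else NA_real_)
}

#' Trajectory entropy
#'
#' Shannon entropy (bits) of the occupancy distribution over a uniform
#' `grid x grid` partition of the focal compartment:
#' `H = -sum_i P_i log2 P_i` with `0 log2 0 = 0`.  Lies in
#' `[0, log2(grid^2)]`; lower values mean more stereotyped swimming.
#'
#' @inheritParams door_time_metrics
#' @return Entropy in bits, or `NA` if no valid sample exists.
#' @export
trajectory_entropy <- function(trial, arena, opts = metric_options()) {
  traj <- scored_window(trial, opts)
  traj <- traj[traj$valid, , drop = FALSE]
  if (!nrow(traj)) return(NA_real_)
  g <- opts$entropy_grid
  bx <- pmin(g, pmax(1, ceiling(traj$x_cm / (arena$focal_len / g))))
  by <- pmin(g, pmax(1, ceiling(traj$y_cm / (arena$width / g))))
  counts <- tabulate((bx - 1) * g + by, nbins = g * g)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Heading error toward the correct door
#'
#' The heading at sample t is the direction of the displacement
#' `x_{t+1} - x_t`; the heading error is the absolute angle (degrees, in
#' `[0, 180]`) between it and the vector from the fish to the correct door's
#' centre.  Samples with displacement speed below `speed_floor` or flagged
#' interpolated are excluded.
#'
#' @inheritParams door_time_metrics
#' @return List with the per-sample series `theta_C` (degrees) and its mean
#'   `theta_C_mean` (`NA` if no moving samples).
#' @export
heading_error <- function(trial, arena, opts = metric_options()) {
  traj <- scored_window(trial, opts)
  n <- nrow(traj)
  if (n < 2) return(list(theta_C = numeric(0), theta_C_mean = NA_real_))
  dt <- traj_dt(trial$trajectory)
  door <- arena$door_centers[trial$correct_door, ]
  hx <- diff(traj$x_cm); hy <- diff(traj$y_cm)
  gx <- door["x"] - traj$x_cm[-n]; gy <- door["y"] - traj$y_cm[-n]
  nh <- sqrt(hx^2 + hy^2); ng <- sqrt(gx^2 + gy^2)
  use <- nh / dt >= opts$speed_floor & ng > 0 &
    !traj$interpolated[-n] & !traj$interpolated[-1] &
    traj$valid[-n] & traj$valid[-1]
  cosang <- pmin(1, pmax(-1, (hx * gx + hy * gy) / (nh * ng)))
  theta <- acos(cosang[use]) * 180 / pi
  list(theta_C = unname(theta),
       theta_C_mean = if (length(theta)) mean(theta) else NA_real_)
}

#' Kinematic summaries: speed, acceleration, turn rate
#'
#' Finite differences on the position series: `v_t = ||x_{t+1} - x_t|| / dt`
#' (cm/s), `a_t = ||v_{t+1} - v_t|| / dt` (cm/s^2, magnitude of the velocity
#' change), and the turn rate
#' `omega_t = acos(v_{t+1} . v_t / (||v_{t+1}|| ||v_t||)) / dt` (rad/s).
#' Turn-rate samples where either velocity norm is below `speed_floor` are
#' excluded; samples touching interpolated positions are excluded from all
#' three.
#'
#' @inheritParams door_time_metrics
#' @return List with `v_mean`, `a_mean`, `omega_mean`.
#' @export
kinematics <- function(trial, arena = NULL, opts = metric_options()) {
  traj <- scored_window(trial, opts)
  n <- nrow(traj)
  if (n < 3)
    return(list(v_mean = NA_real_, a_mean = NA_real_, omega_mean = NA_real_))
  dt <- traj_dt(trial$trajectory)
  vx <- diff(traj$x_cm) / dt; vy <- diff(traj$y_cm) / dt
  sp <- sqrt(vx^2 + vy^2)
  good <- !traj$interpolated & traj$valid
  vok <- good[-n] & good[-1]                       # both endpoints observed
  m <- n - 1
  aok <- vok[-m] & vok[-1]
  ax <- diff(vx) / dt; ay <- diff(vy) / dt
  acc <- sqrt(ax^2 + ay^2)
  dot <- vx[-m] * vx[-1] + vy[-m] * vy[-1]
  den <- sp[-m] * sp[-1]
  wok <- aok & sp[-m] >= opts$speed_floor & sp[-1] >= opts$speed_floor
  omega <- acos(pmin(1, pmax(-1, dot[wok] / den[wok]))) / dt
  list(v_mean = if (any(vok)) mean(sp[vok]) else NA_real_,
       a_mean = if (any(aok)) mean(acc[aok]) else NA_real_,
       omega_mean = if (any(wok)) mean(omega) else NA_real_)
}

#' Freezing time
#'
#' A sample is frozen when the fish moved less than `freezing_threshold`
#' (4 cm) over the rolling `freezing_window` (2 s) centred on it — by
#' default the net displacement between the window's endpoints; edge windows
#' are clipped.  `F = dt x` number of frozen samples.
#'
#' @inheritParams door_time_metrics
#' @return Freezing time in seconds.
#' @export
freezing_time <- function(trial, arena = NULL, opts = metric_options()) {
  traj <- scored_window(trial, opts)
  n <- nrow(traj)
  dt <- traj_dt(trial$trajectory)
  half <- round(opts$freezing_window / 2 / dt)
  j0 <- pmax(1, seq_len(n) - half)
  j1 <- pmin(n, seq_len(n) + half)
  if (opts$freezing_mode == "net") {
    disp <- sqrt((traj$x_cm[j1] - traj$x_cm[j0])^2 +
                   (traj$y_cm[j1] - traj$y_cm[j0])^2)
  } else {
    step <- c(0, cumsum(sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2)))
    disp <- step[j1] - step[j0]
  }
  sum(disp < opts$freezing_threshold) * dt
}

#' Avoidance response after door opening
#'
#' `TRUE` if the distance between the fish and the correct door's centre
#' exceeded two body lengths (6 cm) at any time within the 15 s following
#' door opening; `NA` for censored trials (the door never opened).
#'
#' @inheritParams door_time_metrics
#' @return Logical or `NA`.
#' @export
avoidance_score <- function(trial, arena, opts = metric_options()) {
  if (is.null(trial$T) || is.na(trial$T) || isTRUE(trial$censored))
    return(NA)
  traj <- trial$trajectory
  sel <- traj$t_s > trial$T + 1e-9 &
    traj$t_s <= trial$T + opts$avoidance_window + 1e-9 & traj$valid
  if (!any(sel)) return(NA)
  door <- arena$door_centers[trial$correct_door, ]
  d <- sqrt((traj$x_cm[sel] - door["x"])^2 + (traj$y_cm[sel] - door["y"])^2)
  max(d) > 2 * arena$body_length
}

#' Modified preference index (replica proximity)
#'
#' Fraction of valid time spent in the middle of three equal-area regions
#' along the tank width — the band where the replica stations between the
#' two doors.
#'
#' @inheritParams door_time_metrics
#' @return `PI_m` in `[0, 1]`, `NA` if no valid samples.
#' @export
modified_preference <- function(trial, arena, opts = metric_options()) {
  traj <- scored_window(trial, opts)
  traj <- traj[traj$valid, , drop = FALSE]
  if (!nrow(traj)) return(NA_real_)
  mid <- width_third_zone(arena, "middle")
  mean(zone_contains(mid, cbind(traj$x_cm, traj$y_cm)))
}

#' Compute the full metrics record for one trial
#'
#' Applies every behavioral and learning measure to a completed trial and
#' returns a one-row data frame with the design labels attached; this is the
#' row format of the metrics CSV consumed by the statistics stage.
#'
#' @inheritParams door_time_metrics
#' @return One-row data frame with columns `subject`, `condition`, `batch`,
#'   `sex`, `correct_door`, `door_location`, `session_type`, `trial`,
#'   `test`, `T`, `censored`, `tau_C`, `tau_I`, `PI`, `RI`, `Tw1`-`Tw4`,
#'   `H`, `theta_C`, `v_mean`, `a_mean`, `omega_mean`, `F_freeze`, `A`,
#'   `PI_m`.
#' @export
trial_metrics <- function(trial, arena, opts = metric_options()) {
  dm <- door_time_metrics(trial, arena, opts)
  wm <- wall_metrics(trial, arena, opts)
  he <- heading_error(trial, arena, opts)
  km <- kinematics(trial, arena, opts)
  lab <- function(f, default = NA) {
    v <- trial[[f]]
    if (is.null(v)) default else v
  }
  data.frame(
    subject = lab("subject"), condition = lab("condition"),
    batch = lab("batch"), sex = lab("sex"),
    correct_door = lab("correct_door"),
    door_location = lab("door_location"),
    session_type = lab("session_type"),
    trial = lab("trial"), test = lab("test"),
    T = if (is.null(trial$T)) NA_real_ else trial$T,
    censored = if (is.null(trial$censored)) NA else trial$censored,
    tau_C = dm$tau_C, tau_I = dm$tau_I, PI = dm$PI,
    RI = wm$RI, Tw1 = wm$T_wall[1], Tw2 = wm$T_wall[2],
    Tw3 = wm$T_wall[3], Tw4 = wm$T_wall[4],
    H = trajectory_entropy(trial, arena, opts),
    theta_C = he$theta_C_mean,
    v_mean = km$v_mean, a_mean = km$a_mean, omega_mean = km$omega_mean,
    F_freeze = freezing_time(trial, arena, opts),
    A = avoidance_score(trial, arena, opts),
    PI_m = modified_preference(trial, arena, opts))
}

#' Write a metrics table as CSV
#'
#' One row per trial; undefined values are emitted as empty fields, never
#' as zeros.
#'
#' @param metrics Data frame from [trial_metrics()] rows.
#' @param path Output path.
#' @export
write_metrics_csv <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a metrics CSV
#'
#' @param path Path written by [write_metrics_csv()].
#' @return Data frame with empty fields restored as `NA`.
#' @export
read_metrics_csv <- function(path) {
  read.csv(path, na.strings = "", stringsAsFactors = FALSE)
}
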