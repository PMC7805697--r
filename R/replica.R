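#' Build the replica demonstration schedule
#'
#' Scripts the robotic replica's 10 min demonstration phase of a social
#' training trial.  Each cycle consists of: 30 s of interaction with the
#' confined subject (stochastic swimming attracted to the cylinder centre),
#' a straight transit to the correct door's approach point (P1), 3 s of tail
#' beating there (which opens the door), a pass through the door to P2, a
#' 5 s tail-beating pause, a two-leg return to the focal region (P3, P4),
#' another 30 s interaction, a transit to the incorrect door's approach
#' point, and 3 s of tail beating there (the door stays closed).  After the
#' sixth cycle the replica transits through the correct door to its final
#' station P_F, facing the stimulus group until the phase ends.  Any slack is
#' absorbed into the final station segment so the schedule spans exactly
#' `phase_duration` seconds.
#'
#' @param arena A `bc_arena`.
#' @param correct_door `"lower"` or `"upper"`.
#' @param transit_speed Straight-line transit speed (cm/s); default 10
#'   (about 3.3 BL/s).
#' @param phase_duration Demonstration phase length (s); default 600.
#' @param cycles Demonstration cycles per session; default 6.
#' @param interact_duration,tailbeat_duration,pause_duration Dwell times (s)
#'   of the interaction (30), tail-beating (3), and beyond-door pause (5)
#'   segments.
#' @return A `bc_schedule`: list with `segments` (data frame `start_s`,
#'   `end_s`, `kind`, `target_x_cm`, `target_y_cm`), `cycle_count`,
#'   `phase_duration`, `correct_door`, and the waypoints used.  Segment
#'   kinds: `interact`, `transit`, `tailbeat_correct`, `pass_through`,
#'   `pause_beyond`, `return`, `tailbeat_incorrect`, `final_station`.
#' @examples
#' sched <- build_demo_schedule(make_default_arena(), "lower")
#' sched$cycle_count                       # 6
#' sum(sched$segments$kind == "tailbeat_correct")
#' @export
build_demo_schedule <- function(arena, correct_door = c("lower", "upper"),
                                transit_speed = 10, phase_duration = 600,
                                cycles = 6, interact_duration = 30,
                                tailbeat_duration = 3, pause_duration = 5) {
  correct_door <- match.arg(correct_door)
  if (transit_speed <= 0) stop("transit_speed must be positive")
  incorrect_door <- setdiff(c("lower", "upper"), correct_door)
  approach <- function(door) {
    z <- trigger_zone(arena, door)
    c((z$xmin + z$xmax) / 2, (z$ymin + z$ymax) / 2)
  }
  cyl <- arena$cylinder_center
  p1 <- approach(correct_door)                       # correct-door approach
  y_c <- arena$door_centers[correct_door, "y"]
  p2 <- c(arena$focal_len + arena$trigger_zone_side / 2, y_c)  # beyond door
  p3 <- p1                                           # back on the focal side
  p4 <- cyl + c(arena$cylinder_diameter / 2 + 1, 0)  # near the cylinder
  q1 <- approach(incorrect_door)                     # incorrect-door approach
  pf <- c(arena$focal_len + arena$middle_len / 4, y_c)  # final station

  tt <- function(a, b) sqrt(sum((b - a)^2)) / transit_speed
  segs <- list()
  t <- 0
  add <- function(dur, kind, target) {
    segs[[length(segs) + 1]] <<- data.frame(
      start_s = t, end_s = t + dur, kind = kind,
      target_x_cm = target[1], target_y_cm = target[2])
    t <<- t + dur
  }
  pos <- cyl
  for (k in seq_len(cycles)) {
    add(interact_duration, "interact", cyl);            pos <- cyl
    add(tt(pos, p1), "transit", p1);                    pos <- p1
    add(tailbeat_duration, "tailbeat_correct", p1)
    add(tt(p1, p2), "pass_through", p2);                pos <- p2
    add(pause_duration, "pause_beyond", p2)
    add(tt(p2, p3), "return", p3);                      pos <- p3
    add(tt(p3, p4), "return", p4);                      pos <- p4
    add(interact_duration, "interact", cyl);            pos <- cyl
    add(tt(pos, q1), "transit", q1);                    pos <- q1
    add(tailbeat_duration, "tailbeat_incorrect", q1)
  }
  add(tt(q1, p1), "transit", p1)
  add(tt(p1, pf), "pass_through", pf)
  if (t > phase_duration)
    stop(sprintf(paste("infeasible schedule: %d cycles need %.1f s,",
                       "more than the %g s phase"),
                 cycles, t, phase_duration))
  add(phase_duration - t, "final_station", pf)
  segments <- do.call(rbind, segs)
  structure(list(segments = segments, cycle_count = cycles,
                 phase_duration = phase_duration,
                 correct_door = correct_door,
                 transit_speed = transit_speed,
                 waypoints = list(P1 = p1, P2 = p2, P3 = p3, P4 = p4,
                                  PF = pf, cylinder = cyl)),
            class = "bc_schedule")
}

#' Count door-opening events implied by a schedule
#'
#' The correct door opens once per cycle (for the replica's pass-through) and
#' once more for the final transit to the station position.
#'
#' @param schedule A `bc_schedule`.
#' @return Integer count of door-open events per session.
#' @export
schedule_door_openings <- function(schedule) {
  sum(schedule$segments$kind == "pass_through")
}

#' Realize the replica trajectory for a schedule
#'
#' Produces the replica's position at every tick of the 20 Hz grid over the
#' demonstration phase.  Interaction segments delegate to
#' [simulate_trajectory()] with an attraction point at the cylinder centre;
#' transit/pass/return segments interpolate linearly from the replica's
#' actual position at the segment start to the segment target (so the path
#' is continuous even though interaction segments end at random positions);
#' tail-beat, pause, and station segments hold position at the target.
#'
#' @param schedule A `bc_schedule`.
#' @param params A [swim_params()] object (used by interaction segments).
#' @param arena A `bc_arena`.
#' @param seed Optional seed; the realization is deterministic given it.
#' @return A `bc_trajectory` with identity `"replica"` spanning
#'   `[0, phase_duration]`.
#' @export
replica_trajectory <- function(schedule, params = swim_params(), arena,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- params$dt
  n <- round(schedule$phase_duration / dt)
  tgrid <- seq(0, by = dt, length.out = n + 1)
  x <- numeric(n + 1); y <- numeric(n + 1)
  pos <- schedule$waypoints$cylinder
  x[1] <- pos[1]; y[1] <- pos[2]
  segs <- schedule$segments
  for (s in seq_len(nrow(segs))) {
    i0 <- round(segs$start_s[s] / dt) + 1   # sample at segment start
    i1 <- round(segs$end_s[s] / dt) + 1
    if (i1 <= i0) next
    idx <- (i0 + 1):i1
    target <- c(segs$target_x_cm[s], segs$target_y_cm[s])
    kind <- segs$kind[s]
    if (kind == "interact") {
      sub <- simulate_trajectory(params, arena,
                                 duration = (length(idx)) * dt, start = pos,
                                 attraction_point = target,
                                 bounds = c(0, arena$focal_len, 0,
                                            arena$width),
                                 initial_speed = params$burst_speed_mean,
                                 identity = "replica")
      x[idx] <- sub$x_cm[-1]; y[idx] <- sub$y_cm[-1]
    } else if (kind %in% c("transit", "pass_through", "return")) {
      frac <- (idx - i0) / (i1 - i0)  # hits exactly 1 at the segment end
      x[idx] <- pos[1] + frac * (target[1] - pos[1])
      y[idx] <- pos[2] + frac * (target[2] - pos[2])
    } else {  # tailbeat_*, pause_beyond, final_station hold position
      x[idx] <- target[1]; y[idx] <- target[2]
    }
    pos <- c(x[i1], y[i1])
  }
  new_trajectory(tgrid, x, y, identity = "replica", dt = dt)
}

#' Replica position at arbitrary times
#'
#' Evaluates a realized schedule at time(s) `t` by linear interpolation of
#' the 20 Hz realization (see [replica_trajectory()]).
#'
#' @param schedule A `bc_schedule`.
#' @param t Time(s) in `[0, phase_duration]` (s).
#' @param params,arena,seed Passed to [replica_trajectory()]; alternatively
#'   supply a precomputed realization via `trajectory`.
#' @param trajectory Optional `bc_trajectory` from [replica_trajectory()].
#' @return An n x 2 matrix of positions (cm).
#' @export
replica_position_at <- function(schedule, t, params = swim_params(),
                                arena = NULL, seed = NULL,
                                trajectory = NULL) {
  if (any(t < 0 | t > schedule$phase_duration))
    stop("t outside the demonstration phase")
  if (is.null(trajectory)) {
    if (is.null(arena)) stop("supply either `arena` or `trajectory`")
    trajectory <- replica_trajectory(schedule, params, arena, seed = seed)
  }
  cbind(x = approx(trajectory$t_s, trajectory$x_cm, xout = t)$y,
        y = approx(trajectory$t_s, trajectory$y_cm, xout = t)$y)
}

#' Export a schedule's segments as CSV
#'
#' Columns: `start_s,end_s,kind,target_x_cm,target_y_cm`.
#'
#' @param schedule A `bc_schedule`.
#' @param path Output file path.
#' @export
write_schedule_csv <- function(schedule, path) {
  write.csv(schedule$segments, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
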