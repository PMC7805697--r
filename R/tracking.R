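#' Tracker configuration
#'
#' @param threshold Gray-level threshold on the absolute frame difference
#'   (0-255 scale; default 10).
#' @param min_area Minimum blob area in px^2 after morphology.
#' @param close_radius Radius (px) of the morphological closing.
#' @param gate_cm Gating radius (cm) for matching a detection to the
#'   commanded replica position or to a track prediction.
#' @param horizon_s Maximum Kalman extrapolation horizon (s); beyond it the
#'   last estimate is held and samples are marked invalid.
#' @param process_sd Kalman process (acceleration) noise SD (cm/s^2).
#' @param meas_sd Kalman measurement noise SD (cm).
#' @param dt Frame interval (s).
#' @return A `bc_tracker_config` list.
#' @export
tracker_config <- function(threshold = 10, min_area = 20, close_radius = 1,
                           gate_cm = 5, horizon_s = 1, process_sd = 200,
                           meas_sd = 0.2, dt = 0.05) {
  structure(as.list(environment()), class = "bc_tracker_config")
}

#' Detect moving blobs by frame differencing
#'
#' Implements the detection chain of the live tracker: absolute difference
#' of two consecutive grayscale frames, fixed threshold, morphological
#' closing, hole filling, connected components, area filter, and centroid
#' extraction.  Because consecutive frames are differenced, a detection marks
#' the union of the fish's old and new silhouettes; its centroid sits between
#' the two positions (within half a displacement of either).
#'
#' @param frame_a,frame_b Integer matrices (0-255 gray levels, same shape).
#' @param cfg A [tracker_config()].
#' @param calib Calibration from [render_frames()]; if supplied, centroids
#'   are also mapped to cm.
#' @return A `bc_detection`: list with `centroids_px` (k x 2, col/row),
#'   `centroids_cm` (k x 2 or NULL), and `areas` (px^2).
#' @export
detect_blobs <- function(frame_a, frame_b, cfg = tracker_config(),
                         calib = NULL) {
  if (!all(dim(frame_a) == dim(frame_b)))
    stop("frames must have the same shape")
  d <- abs(frame_b - frame_a)
  mask <- matrix(as.integer(d >= cfg$threshold), nrow = nrow(d))
  if (cfg$close_radius > 0) {
    mask <- bc_dilate_cpp(mask, cfg$close_radius)
    mask <- bc_erode_cpp(mask, cfg$close_radius)
  }
  mask <- bc_fill_holes_cpp(mask)
  lab <- bc_label_cpp(mask)
  k <- max(lab)
  if (k == 0) {
    return(structure(list(centroids_px = matrix(numeric(0), ncol = 2),
                          centroids_cm = NULL, areas = numeric(0)),
                     class = "bc_detection"))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[idx]
  areas <- tabulate(labs, nbins = k)
  rows <- vapply(split(idx[, 1], labs), mean, 0)
  cols <- vapply(split(idx[, 2], labs), mean, 0)
  keep <- areas >= cfg$min_area
  centroids_px <- cbind(col = cols[keep], row = rows[keep])
  structure(list(
    centroids_px = centroids_px,
    centroids_cm = if (!is.null(calib) && nrow(centroids_px))
      px_to_cm(centroids_px, calib) else NULL,
    areas = areas[keep]), class = "bc_detection")
}

# --- constant-velocity Kalman filter (state: x, y, vx, vy) ----------------

kalman_new <- function(pos, cfg) {
  list(x = c(pos[1], pos[2], 0, 0),
       P = diag(c(cfg$meas_sd^2, cfg$meas_sd^2, 25, 25)),
       last_seen = 0)
}

kalman_predict <- function(ks, cfg) {
  dt <- cfg$dt
  F_ <- diag(4); F_[1, 3] <- dt; F_[2, 4] <- dt
  gx <- c(dt^2 / 2, 0, dt, 0)  # white-acceleration noise, per axis
  gy <- c(0, dt^2 / 2, 0, dt)
  Q <- cfg$process_sd^2 * (gx %o% gx + gy %o% gy)
  ks$x <- as.numeric(F_ %*% ks$x)
  ks$P <- F_ %*% ks$P %*% t(F_) + Q
  ks
}

kalman_update <- function(ks, z, cfg) {
  H <- matrix(c(1, 0, 0, 0, 0, 1, 0, 0), nrow = 2, byrow = TRUE)
  R <- diag(cfg$meas_sd^2, 2)
  S <- H %*% ks$P %*% t(H) + R
  K <- ks$P %*% t(H) %*% solve(S)
  ks$x <- as.numeric(ks$x + K %*% (z - H %*% ks$x))
  ks$P <- (diag(4) - K %*% H) %*% ks$P
  ks
}

#' Create a fresh multi-identity track state
#'
#' @param identities Character vector of identities to track (subset of
#'   `"subject"`, `"replica"`).
#' @return A `bc_track_state` used/updated by [assign_identities()].
#' @export
track_state <- function(identities = "subject") {
  structure(list(filters = setNames(vector("list", length(identities)),
                                    identities),
                 missed = setNames(rep(0, length(identities)), identities)),
            class = "bc_track_state")
}

#' Assign detections to identities and advance the track state
#'
#' The detection nearest the commanded replica position (within the gating
#' radius) is labelled replica — the live system disambiguates fish and
#' replica using the input to the Cartesian plotter.  Of the remaining
#' detections, the one nearest the subject's Kalman prediction is the
#' subject.  Identities without a matched detection are advanced by the
#' Kalman predictor and their output flagged `interpolated`; beyond the
#' extrapolation horizon the last estimate is held and flagged invalid.
#'
#' @param det A `bc_detection` with `centroids_cm`.
#' @param state A [track_state()].
#' @param replica_command Optional commanded replica position `c(x, y)` cm.
#' @param cfg A [tracker_config()].
#' @return The updated state, with an `estimates` field: one row per
#'   identity (`x`, `y`, `interpolated`, `valid`).
#' @export
assign_identities <- function(det, state, replica_command = NULL,
                              cfg = tracker_config()) {
  cent <- det$centroids_cm
  avail <- if (is.null(cent)) integer(0) else seq_len(nrow(cent))
  ids <- names(state$filters)
  est <- data.frame(identity = ids, x = NA_real_, y = NA_real_,
                    interpolated = FALSE, valid = TRUE)

  take <- function(target) {
    if (!length(avail) || is.null(target)) return(NA_integer_)
    d <- sqrt((cent[avail, 1] - target[1])^2 +
                (cent[avail, 2] - target[2])^2)
    j <- which.min(d)
    if (d[j] > cfg$gate_cm) return(NA_integer_)
    i <- avail[j]
    avail <<- avail[-j]
    i
  }

  # replica first: it is identified from the commanded position
  order_ids <- ids[order(ids != "replica")]
  for (id in order_ids) {
    ks <- state$filters[[id]]
    target <- if (id == "replica" && !is.null(replica_command))
      replica_command
    else if (!is.null(ks)) ks$x[1:2]
    else if (length(avail)) cent[avail[1], ]   # bootstrap: first detection
    else NULL
    if (!is.null(ks)) ks <- kalman_predict(ks, cfg)
    i <- take(target)
    if (!is.na(i)) {
      z <- cent[i, ]
      ks <- if (is.null(ks)) kalman_new(z, cfg) else kalman_update(ks, z, cfg)
      state$missed[[id]] <- 0
    } else if (!is.null(ks)) {
      state$missed[[id]] <- state$missed[[id]] + 1
      row <- match(id, ids)
      est$interpolated[row] <- TRUE
      if (state$missed[[id]] * cfg$dt > cfg$horizon_s) {
        ks$x[3:4] <- 0  # hold last estimate
        est$valid[row] <- FALSE
      }
    }
    state$filters[[id]] <- ks
    row <- match(id, ids)
    if (!is.null(ks)) { est$x[row] <- ks$x[1]; est$y[row] <- ks$x[2] }
    else est$valid[row] <- FALSE
  }
  state$estimates <- est
  state
}

#' Track a frame sequence
#'
#' Runs [detect_blobs()] on consecutive frame pairs, maintains the track
#' state with [assign_identities()], and returns one trajectory per identity
#' on the uniform frame grid.  The estimate for frame i comes from the
#' difference of frames i-1 and i; the first frame's sample repeats the
#' first available estimate and is flagged interpolated.
#'
#' @param frames A `bc_frames` object (rendered or read from PNG).
#' @param cfg A [tracker_config()].
#' @param identities Identities to track.
#' @param replica_commands Optional n x 2 matrix of commanded replica
#'   positions (cm), one row per frame.
#' @return Named list of `bc_trajectory` objects.
#' @export
track_video <- function(frames, cfg = tracker_config(),
                        identities = "subject", replica_commands = NULL) {
  n <- length(frames$frames)
  if (n < 2) stop("need at least 2 frames")
  state <- track_state(identities)
  out <- lapply(identities, function(id)
    list(x = rep(NA_real_, n), y = rep(NA_real_, n),
         interp = rep(TRUE, n), valid = rep(FALSE, n)))
  names(out) <- identities
  for (i in 2:n) {
    det <- detect_blobs(frames$frames[[i - 1]], frames$frames[[i]], cfg,
                        frames$calib)
    cmd <- if (!is.null(replica_commands)) replica_commands[i, ] else NULL
    state <- assign_identities(det, state, replica_command = cmd, cfg = cfg)
    for (id in identities) {
      row <- match(id, state$estimates$identity)
      out[[id]]$x[i] <- state$estimates$x[row]
      out[[id]]$y[i] <- state$estimates$y[row]
      out[[id]]$interp[i] <- state$estimates$interpolated[row]
      out[[id]]$valid[i] <- state$estimates$valid[row]
    }
  }
  dt <- median(diff(frames$t_s))
  res <- lapply(seq_along(out), function(k) {
    o <- out[[k]]
    first <- which(!is.na(o$x))[1]
    if (is.na(first))
      stop("no detections for identity '", identities[k],
           "' in the sequence")
    back <- seq_len(first - 1)
    o$x[back] <- o$x[first]; o$y[back] <- o$y[first]
    o$valid[back] <- TRUE
    new_trajectory(frames$t_s, o$x, o$y, identity = identities[k],
                   valid = o$valid, interpolated = o$interp, dt = dt)
  })
  names(res) <- identities
  res
}

#' Door trigger rule
#'
#' The door opens at the earliest time at which the subject has been present
#' in the trigger zone for at least `required_s` seconds out of the trailing
#' `window_s` seconds.  Presence is a logical series sampled at the frame
#' rate; sample i covers the interval `((i-1) dt, i dt]`, so 60 consecutive
#' presence samples from the start trigger at exactly 3.0 s.  Windows
#' shorter than `window_s` at the start are clipped to the elapsed time (so
#' continuous presence can trigger before 5 s have elapsed).
#'
#' @param presence Logical vector sampled uniformly at `1/dt` Hz.
#' @param dt Sample interval (s); default 0.05 (20 Hz).
#' @param window_s Trailing window length (s); default 5.
#' @param required_s Required presence within the window (s); default 3.
#' @return The trigger time in seconds (from the start of the series), or
#'   `NA_real_` if the rule is never satisfied.
#' @examples
#' evaluate_trigger(rep(TRUE, 100))                 # 3.0
#' evaluate_trigger(rep(c(TRUE, FALSE), 50))        # NA
#' @export
evaluate_trigger <- function(presence, dt = 0.05, window_s = 5,
                             required_s = 3) {
  if (anyNA(presence)) stop("presence series must not contain NA")
  presence <- as.logical(presence)
  w <- round(window_s / dt)
  need <- round(required_s / dt)
  cs <- cumsum(presence)
  n <- length(presence)
  lag <- c(rep(0, min(w, n)), cs[seq_len(max(0, n - w))])
  counts <- cs - lag
  hit <- which(counts >= need)
  if (!length(hit)) NA_real_ else hit[1] * dt
}

#' Run the trial session state machine
#'
#' Builds the trigger-zone presence series from the subject trajectory,
#' applies the door trigger rule from the moment of release, and produces
#' the completed trial record: on trigger, a door-open event is recorded and
#' `T` is the time from release to opening; otherwise the trial is
#' right-censored at the time limit (`T = time_limit`).  The 2 min reward
#' period after opening is recorded as a close event; it contributes no
#' metrics.  For doors-closed test sessions (`doors_active = FALSE`) no
#' trigger is evaluated and `T` is `NA`.
#'
#' @param trial A `bc_trial` from [simulate_trial()], or a `bc_trajectory`
#'   (in which case `correct_door` must be given and default labels are
#'   attached).
#' @param arena A `bc_arena`.
#' @param correct_door Required when `trial` is a bare trajectory.
#' @param release_time Time of release from the cylinder on the trajectory
#'   clock (s); default 0.
#' @param time_limit Right-censoring limit (s); default 1800 (30 min).
#' @param reward_duration Reward-period length (s); default 120.
#' @return The `bc_trial` with `T`, `censored`, and `events` filled in.
#' @export
run_trial_session <- function(trial, arena, correct_door = NULL,
                              release_time = 0, time_limit = 1800,
                              reward_duration = 120) {
  if (inherits(trial, "bc_trajectory")) {
    if (is.null(correct_door))
      stop("correct_door is required when passing a bare trajectory")
    trial <- structure(list(trajectory = trial, correct_door = correct_door,
                            session_type = "training", doors_active = TRUE,
                            release_duration = max(trial$t_s) - release_time,
                            T = NA_real_, censored = NA, events = NULL),
                       class = "bc_trial")
  }
  traj <- trial$trajectory
  dt <- traj_dt(traj)
  if (!isTRUE(trial$doors_active)) {
    trial$T <- NA_real_
    trial$censored <- NA
    trial$events <- data.frame(t_s = numeric(0), door_id = character(0),
                               event = character(0))
    return(trial)
  }
  zone <- trigger_zone(arena, trial$correct_door)
  sel <- traj$t_s > release_time + 1e-9
  if (!any(sel)) stop("trajectory does not cover the release phase")
  pos <- cbind(traj$x_cm[sel], traj$y_cm[sel])
  presence <- zone_contains(zone, pos) & traj$valid[sel]
  covered <- max(traj$t_s) - release_time
  tt <- evaluate_trigger(presence, dt = dt)
  if (!is.na(tt) && tt <= time_limit) {
    trial$T <- tt
    trial$censored <- FALSE
    trial$events <- data.frame(
      t_s = release_time + c(tt, tt + reward_duration),
      door_id = trial$correct_door, event = c("open", "close"))
  } else {
    if (covered < time_limit - 1e-9)
      stop(sprintf(paste("trajectory covers only %.1f s of the %.0f s",
                         "release phase and never triggered:",
                         "cannot establish censoring"), covered, time_limit))
    trial$T <- time_limit
    trial$censored <- TRUE
    trial$events <- data.frame(t_s = numeric(0), door_id = character(0),
                               event = character(0))
  }
  trial
}

#' Write door events as CSV (`t_s,door_id,event`)
#'
#' @param trial A completed `bc_trial`.
#' @param path Output path.
#' @export
write_events_csv <- function(trial, path) {
  write.csv(trial$events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
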