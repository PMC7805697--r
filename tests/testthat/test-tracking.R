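# straight-line constant-velocity trajectory for controlled fixtures
line_traj <- function(from, to, duration, dt = 0.05) {
  n <- round(duration / dt)
  fr <- seq(0, 1, length.out = n + 1)
  new_trajectory(seq(0, by = dt, length.out = n + 1),
                 from[1] + fr * (to[1] - from[1]),
                 from[2] + fr * (to[2] - from[2]), dt = dt)
}

test_that("trigger rule matches examples and the brute-force oracle", {
  # 3 s of continuous presence from the start
  expect_equal(evaluate_trigger(rep(TRUE, 100)), 3.0)
  # periodic 2.9 s in / 2.1 s out never reaches 60 samples in any window
  pat <- rep(c(rep(TRUE, 58), rep(FALSE, 42)), 20)
  expect_true(is.na(evaluate_trigger(pat)))
  expect_error(evaluate_trigger(c(TRUE, NA, TRUE)), "NA")
  set.seed(31)
  for (k in 1:1000) {
    presence <- runif(sample(30:300, 1)) < runif(1, 0.3, 0.8)
    expect_identical(evaluate_trigger(presence),
                     oracle_trigger(presence))
  }
})

test_that("trigger rule is monotone in presence", {
  set.seed(17)
  for (k in 1:200) {
    presence <- runif(200) < 0.55
    t0 <- evaluate_trigger(presence)
    more <- presence
    more[sample(which(!presence), 5)] <- TRUE
    t1 <- evaluate_trigger(more)
    if (!is.na(t0)) {
      expect_false(is.na(t1))
      expect_lte(t1, t0)
    }
  }
})

test_that("identical frames yield no detections; shape mismatch errors", {
  f <- matrix(255L, 60, 60)
  d <- detect_blobs(f, f)
  expect_equal(nrow(d$centroids_px), 0)
  expect_error(detect_blobs(f, matrix(255L, 50, 60)), "same shape")
})

test_that("rendered moving blob is detected within 1 px of ground truth", {
  a <- default_arena
  tr <- line_traj(c(10, 10), c(13, 16), duration = 1)
  fr <- render_frames(tr, a, resolution = c(320, 320),
                      region = c(0, 30, 0, 30), wobble_amp = 0.15)
  for (i in c(5, 10, 15)) {
    d <- detect_blobs(fr$frames[[i - 1]], fr$frames[[i]], calib = fr$calib)
    expect_equal(nrow(d$centroids_px), 1)
    # a detection marks the union of the two paired silhouettes: its
    # centroid must land within 1 px of one of the two true positions
    gt <- cm_to_px(cbind(tr$x_cm[c(i - 1, i)], tr$y_cm[c(i - 1, i)]),
                   fr$calib)
    err <- min(sqrt(rowSums((gt - rep(d$centroids_px[1, ],
                                      each = 2))^2)))
    expect_lt(err, 1)
  }
})

test_that("two well-separated moving blobs give two detections", {
  a <- default_arena
  t1 <- line_traj(c(8, 8), c(10, 8), duration = 1)
  t2 <- line_traj(c(22, 22), c(20, 22), duration = 1)
  fr <- render_frames(list(t1, t2), a, resolution = c(320, 320),
                      region = c(0, 30, 0, 30), wobble_amp = 0.15)
  d <- detect_blobs(fr$frames[[5]], fr$frames[[6]], calib = fr$calib)
  expect_equal(nrow(d$centroids_px), 2)
})

test_that("renderer validates resolution and draws centred symmetric blobs", {
  a <- default_arena
  tr <- line_traj(c(15, 15), c(15, 15), duration = 0.5)
  expect_error(render_frames(tr, a, resolution = c(40, 16)),
               "resolution too low")
  fr <- render_frames(tr, a, resolution = c(320, 320),
                      region = c(0, 30, 0, 30))
  # stationary fish: consecutive frames identical without wobble/noise
  expect_identical(fr$frames[[1]], fr$frames[[2]])
  # blob centroid within 1 px of the projected ground-truth position
  mask <- which(fr$frames[[1]] < 255, arr.ind = TRUE)
  ctr_px <- c(mean(mask[, 2]), mean(mask[, 1]))  # (col, row)
  truth <- cm_to_px(cbind(15, 15), fr$calib)
  expect_lt(sqrt(sum((ctr_px - truth[1, ])^2)), 1)
})

test_that("frame PNG round trip preserves pixels and calibration", {
  a <- default_arena
  tr <- line_traj(c(10, 12), c(12, 12), duration = 0.25)
  fr <- render_frames(tr, a, resolution = c(160, 160),
                      region = c(0, 30, 0, 30))
  dir <- tempfile("frames")
  write_frames_png(fr, dir)
  back <- read_frames_png(dir)
  expect_equal(length(back$frames), length(fr$frames))
  expect_equal(back$frames[[3]], fr$frames[[3]])
  expect_equal(back$calib$px_per_cm, fr$calib$px_per_cm)
  expect_equal(back$t_s, fr$t_s)
  unlink(dir, recursive = TRUE)
})

test_that("tracker reconstructs a clean fixture below 0.5 cm RMSE", {
  a <- default_arena
  p <- swim_params()
  tr <- simulate_trajectory(p, a, 6, start = c(15, 15),
                            bounds = c(4, 26, 4, 26), seed = 3,
                            initial_speed = 10)
  fr <- render_frames(tr, a, resolution = c(320, 320),
                      region = c(0, 30, 0, 30), wobble_amp = 0.15)
  out <- track_video(fr)
  expect_named(out, "subject")
  tt <- out$subject
  expect_equal(nrow(tt), length(fr$frames))     # one sample per frame
  err <- sqrt((tt$x_cm - tr$x_cm)^2 + (tt$y_cm - tr$y_cm)^2)
  expect_lt(sqrt(mean(err^2)), 0.5)
  expect_error(track_video(list(frames = fr$frames[1])), "2 frames")
})

test_that("blanked frames are gap-filled by the Kalman predictor", {
  a <- default_arena
  tr <- line_traj(c(8, 15), c(20, 15), duration = 5)
  fr <- render_frames(tr, a, resolution = c(320, 320),
                      region = c(0, 30, 0, 30), wobble_amp = 0.15)
  blank <- matrix(255L, 320, 320)
  drop_idx <- 50:54
  for (i in drop_idx) fr$frames[[i]] <- blank
  tt <- track_video(fr)$subject
  expect_equal(nrow(tt), length(fr$frames))     # no grid gaps
  expect_true(all(diff(tt$t_s) - 0.05 < 1e-9))
  # frames whose pair touches a blank frame are extrapolated and flagged
  expect_true(all(tt$interpolated[51:54]))
  err <- abs(tt$x_cm[drop_idx] - tr$x_cm[drop_idx])
  expect_lt(max(err), 1)                        # constant-velocity fill
  expect_true(all(tt$valid[drop_idx]))          # within the 1 s horizon
})

test_that("commanded replica position prevents identity swaps at crossing", {
  a <- default_arena
  sub <- line_traj(c(8, 10), c(22, 20), duration = 4)
  rep_ <- line_traj(c(22, 10), c(8, 20), duration = 4)
  fr <- render_frames(list(sub, rep_), a, resolution = c(320, 320),
                      region = c(0, 30, 0, 30), wobble_amp = 0.15)
  out <- track_video(fr, identities = c("subject", "replica"),
                     replica_commands = cbind(rep_$x_cm, rep_$y_cm))
  n <- nrow(sub)
  # after the crossing each track ends on its own target
  d_sub <- sqrt((out$subject$x_cm[n] - sub$x_cm[n])^2 +
                  (out$subject$y_cm[n] - sub$y_cm[n])^2)
  d_rep <- sqrt((out$replica$x_cm[n] - rep_$x_cm[n])^2 +
                  (out$replica$y_cm[n] - rep_$y_cm[n])^2)
  expect_lt(d_sub, 2)
  expect_lt(d_rep, 2)
  # single detection with no replica command goes to the subject
  det <- detect_blobs(fr$frames[[5]], fr$frames[[6]], calib = fr$calib)
  st <- assign_identities(det, track_state("subject"))
  expect_false(st$estimates$interpolated[1])
  # zero detections: estimate comes from the Kalman prediction, flagged
  st2 <- assign_identities(
    structure(list(centroids_px = matrix(numeric(0), ncol = 2),
                   centroids_cm = NULL, areas = numeric(0)),
              class = "bc_detection"), st)
  expect_true(st2$estimates$interpolated[1])
  expect_equal(st2$estimates$x[1], st$estimates$x[1], tolerance = 1)
})

test_that("run_trial_session applies the trigger rule and censoring", {
  a <- default_arena
  # parked inside the correct trigger zone from release
  parked <- make_trial(rep(27, 200), rep(7.5, 200))
  done <- run_trial_session(parked, a, time_limit = 1800,
                            release_time = 0)
  expect_equal(done$T, 3.0)
  expect_false(done$censored)
  expect_equal(done$events$event, c("open", "close"))
  expect_equal(done$events$t_s, c(3, 123))
  # never entering the zone for the whole limit: censored at the limit
  away <- make_trial(rep(5, 121), rep(15, 121), dt = 0.05)
  expect_error(run_trial_session(away, a, time_limit = 1800),
               "cannot establish censoring")
  away_long <- make_trial(rep(5, 36001), rep(15, 36001))
  done2 <- run_trial_session(away_long, a, time_limit = 1800)
  expect_equal(done2$T, 1800)
  expect_true(done2$censored)
  expect_equal(nrow(done2$events), 0)
})

test_that("session trigger equals an offline brute-force pass", {
  a <- default_arena
  p <- swim_params(attraction_gain = 0.6)
  for (s in 1:5) {
    tr <- simulate_trajectory(p, a, 300, start = c(15, 15),
                              attraction_point = c(27, 22.5),
                              bounds = c(0, 30, 0, 30), seed = 600 + s)
    trial <- run_trial_session(
      make_trial(tr$x_cm, tr$y_cm, correct_door = "upper"), a,
      time_limit = 300)
    z <- trigger_zone(a, "upper")
    presence <- tr$x_cm >= z$xmin & tr$x_cm <= z$xmax &
      tr$y_cm >= z$ymin & tr$y_cm <= z$ymax
    oracle <- oracle_trigger(presence[-1])
    if (is.na(oracle)) expect_true(trial$censored)
    else expect_equal(trial$T, oracle)
    if (!trial$censored) expect_gte(trial$T, 3.0)
  }
})
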