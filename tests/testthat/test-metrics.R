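test_that("door-time metrics reproduce the worked examples", {
  a <- default_arena
  # 600 samples (30 s) in the correct zone, 200 (10 s) in the incorrect
  x <- c(rep(27, 600), rep(27, 200), rep(10, 200))
  y <- c(rep(7.5, 600), rep(22.5, 200), rep(15, 200))
  m <- door_time_metrics(make_trial(x, y), a)
  expect_equal(m$tau_C, 30)
  expect_equal(m$tau_I, 10)
  expect_equal(m$PI, 0.75)
  # equal times give no preference
  m2 <- door_time_metrics(make_trial(c(rep(27, 100), rep(27, 100)),
                                     c(rep(7.5, 100), rep(22.5, 100))), a)
  expect_equal(m2$PI, 0.5)
  # never near either door: undefined, not zero
  m3 <- door_time_metrics(make_trial(rep(10, 50), rep(15, 50)), a)
  expect_true(is.na(m3$PI))
  # truncation at door opening; the boundary sample at t = T is included
  tr4 <- make_trial(x, y, T = 30, censored = FALSE)
  m4 <- door_time_metrics(tr4, a)
  expect_equal(m4$tau_C, 30)
  expect_equal(m4$tau_I, 0.05)
})

test_that("wall metrics reproduce the symmetry examples", {
  a <- default_arena
  # equal time at the centres of the four wall bands
  x <- c(rep(29, 100), rep(1, 100), rep(15, 100), rep(15, 100))
  y <- c(rep(15, 100), rep(15, 100), rep(1, 100), rep(29, 100))
  m <- wall_metrics(make_trial(x, y), a)
  expect_equal(m$T_wall, rep(5, 4))
  expect_equal(m$RI, 0.25)
  m2 <- wall_metrics(make_trial(rep(29, 100), rep(15, 100)), a)
  expect_equal(m2$RI, 1)
  m3 <- wall_metrics(make_trial(rep(15, 50), rep(15, 50)), a)
  expect_true(is.na(m3$RI))
})

test_that("entropy attains its extremes and stays in bounds", {
  a <- default_arena
  expect_equal(trajectory_entropy(make_trial(rep(4.2, 100),
                                             rep(4.2, 100)), a), 0)
  # two equally occupied bins -> 1 bit
  two <- make_trial(rep(c(1.5, 28.5), 100), rep(15.5, 200))
  expect_equal(trajectory_entropy(two, a), 1)
  # uniform occupancy over all 100 bins -> log2(100)
  ctrs <- seq(1.5, 28.5, by = 3)
  grid <- expand.grid(x = ctrs, y = ctrs)
  uni <- make_trial(grid$x, grid$y)
  expect_equal(trajectory_entropy(uni, a), log2(100))
  for (s in 1:20) {
    h <- trajectory_entropy(random_trial(s), a)
    expect_gte(h, 0)
    expect_lte(h, log2(100))
  }
})

test_that("heading error is 0 toward the door and 180 away", {
  a <- default_arena
  # swims straight at the lower door centre (30, 7.5)
  toward <- make_trial(seq(10, 20, by = 0.25),
                       7.5 + (30 - seq(10, 20, by = 0.25)) * 0)
  # direct line toward the door from (10, 7.5)
  n <- 41
  xt <- seq(10, 20, length.out = n)
  tow <- make_trial(xt, rep(7.5, n))
  expect_equal(heading_error(tow, a)$theta_C_mean, 0, tolerance = 1e-10)
  awy <- make_trial(rev(xt), rep(7.5, n))
  expect_equal(heading_error(awy, a)$theta_C_mean, 180, tolerance = 1e-10)
  # no moving samples: undefined
  still <- make_trial(rep(12, 50), rep(12, 50))
  expect_true(is.na(heading_error(still, a)$theta_C_mean))
})

test_that("kinematics reproduce the finite-difference examples", {
  a <- default_arena
  # points 1 cm apart at dt = 0.05 -> v = 20 cm/s; constant velocity ->
  # zero acceleration and turn rate
  n <- 30
  cv <- make_trial(seq(0, by = 1, length.out = n), rep(15, n))
  k <- kinematics(cv)
  expect_equal(k$v_mean, 20)
  expect_equal(k$a_mean, 0)
  expect_equal(k$omega_mean, 0)
  # right-angle turn at 1 cm/s: omega = (pi/2) / dt
  rt <- make_trial(c(0, 0.05, 0.05), c(10, 10, 10.05))
  k2 <- kinematics(rt)
  expect_equal(k2$omega_mean, (pi / 2) / 0.05, tolerance = 1e-9)
  expect_equal(k2$a_mean, sqrt(2) / 0.05, tolerance = 1e-9)
  expect_equal(k2$v_mean, 1, tolerance = 1e-9)
})

test_that("freezing time covers the stationary and cruising extremes", {
  a <- default_arena
  still <- make_trial(rep(3, 200), rep(3, 200))   # 200 samples = 10 s
  expect_equal(freezing_time(still), 10)
  # straight swim at 5 cm/s covers 10 cm per 2 s window: never frozen
  n <- 201
  cruise <- make_trial(seq(0, by = 0.25, length.out = n), rep(15, n))
  expect_equal(freezing_time(cruise), 0)
})

test_that("avoidance scoring follows the 2 BL rule", {
  a <- default_arena
  dt <- 0.05
  # trigger at T = 3, then retreat to 7 cm from the door centre
  n_pre <- 100; n_post <- 300
  x <- c(rep(28, n_pre), rep(23.2, n_post))
  y <- c(rep(7.5, n_pre), rep(7.5, n_post))
  tr <- make_trial(x, y, T = 3, censored = FALSE)
  expect_true(avoidance_score(tr, a))     # 30 - 23.2 = 6.8 > 6
  x2 <- c(rep(28, n_pre), rep(26, n_post))
  tr2 <- make_trial(x2, y, T = 3, censored = FALSE)
  expect_false(avoidance_score(tr2, a))   # stays within 5 cm
  cens <- make_trial(rep(5, 100), rep(5, 100), T = 1800, censored = TRUE)
  expect_true(is.na(avoidance_score(cens, a)))
})

test_that("modified preference index matches the thirds examples", {
  a <- default_arena
  mid <- make_trial(rep(15, 80), rep(15, 80))
  expect_equal(modified_preference(mid, a), 1)
  yy <- rep(seq(0.5, 29.5, by = 1), 3)
  uni <- make_trial(rep(15, length(yy)), yy)
  expect_equal(modified_preference(uni, a), 1 / 3)
})

test_that("every metric equals its naive per-sample oracle on random trajectories", {
  a <- default_arena
  opts <- metric_options()
  for (s in 1:100) {
    trial <- random_trial(s, n = 150)
    if (s %% 3 == 0) { trial$T <- 5; trial$censored <- FALSE }
    dm <- door_time_metrics(trial, a, opts)
    om <- oracle_door_times(trial, a)
    expect_equal(dm$tau_C, om$tau_C)
    expect_equal(dm$tau_I, om$tau_I)
    expect_equal(dm$PI, om$PI)
    wm <- wall_metrics(trial, a, opts)
    ow <- oracle_wall_times(trial, a)
    expect_equal(wm$T_wall, ow$T_wall)
    expect_equal(wm$RI, ow$RI)
    expect_equal(trajectory_entropy(trial, a, opts),
                 oracle_entropy(trial, a))
    expect_equal(heading_error(trial, a, opts)$theta_C_mean,
                 oracle_heading(trial, a))
    km <- kinematics(trial, a, opts)
    ok <- oracle_kinematics(trial)
    expect_equal(km$v_mean, ok$v_mean)
    expect_equal(km$a_mean, ok$a_mean)
    expect_equal(km$omega_mean, ok$omega_mean)
    expect_equal(freezing_time(trial, a, opts), oracle_freezing(trial))
    expect_equal(modified_preference(trial, a, opts),
                 oracle_thirds(trial, a))
  }
})

test_that("metrics are invariant under width reflection with door relabeling", {
  a <- default_arena
  for (s in c(3, 14, 27)) {
    trial <- random_trial(s, n = 300, correct_door = "lower")
    refl <- trial
    refl$trajectory$y_cm <- a$width - trial$trajectory$y_cm
    refl$correct_door <- "upper"
    m1 <- trial_metrics(trial, a)
    m2 <- trial_metrics(refl, a)
    for (col in c("tau_C", "tau_I", "PI", "RI", "H", "theta_C", "v_mean",
                  "a_mean", "omega_mean", "F_freeze", "PI_m"))
      expect_equal(m1[[col]], m2[[col]], tolerance = 1e-9,
                   label = paste("reflected", col))
  }
})

test_that("interpolated samples are excluded from kinematic metrics only", {
  a <- default_arena
  trial <- random_trial(5, n = 120)
  interp <- rep(FALSE, 120); interp[40:60] <- TRUE
  trial$trajectory$interpolated <- interp
  km <- kinematics(trial, a)
  ok <- oracle_kinematics(trial)
  expect_equal(km$v_mean, ok$v_mean)
  expect_equal(km$omega_mean, ok$omega_mean)
  # occupancy-based metrics still count interpolated samples
  expect_equal(trajectory_entropy(trial, a), oracle_entropy(trial, a))
})

test_that("time fractions stay in [0, 1] and durations below the phase", {
  a <- default_arena
  for (s in 1:20) {
    trial <- random_trial(s, n = 200)
    m <- trial_metrics(trial, a)
    dur <- 200 * 0.05
    for (col in c("PI", "RI", "PI_m"))
      if (!is.na(m[[col]])) {
        expect_gte(m[[col]], 0); expect_lte(m[[col]], 1)
      }
    expect_lte(m$tau_C + m$tau_I, 2 * dur)
    expect_lte(m$F_freeze, dur + 0.05)
    expect_lte(max(m$Tw1, m$Tw2, m$Tw3, m$Tw4), dur + 0.05)
  }
})

test_that("metrics CSV round trip preserves NA as empty fields", {
  a <- default_arena
  at_doors <- make_trial(c(rep(27, 60), rep(27, 20)),
                         c(rep(7.5, 60), rep(22.5, 20)))
  rows <- rbind(trial_metrics(at_doors, a),
                trial_metrics(make_trial(rep(10, 50), rep(15, 50)), a))
  f <- tempfile(fileext = ".csv")
  write_metrics_csv(rows, f)
  txt <- readLines(f)
  expect_false(any(grepl("NA", txt)))   # undefined emitted as empty
  back <- read_metrics_csv(f)
  expect_true(is.na(back$PI[2]))
  expect_equal(back$PI[1], rows$PI[1], tolerance = 1e-12)
  unlink(f)
})
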