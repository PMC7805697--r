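# Shared fixtures and independent brute-force oracles.  Oracles are written
# as plain per-sample loops, deliberately independent of the vectorized
# implementations they check.

default_arena <- make_default_arena()

# Build a trial record directly from coordinate vectors.
make_trial <- function(x, y, dt = 0.05, correct_door = "lower",
                       T = NA_real_, censored = NA, valid = TRUE,
                       interpolated = FALSE, doors_active = TRUE) {
  traj <- new_trajectory(seq(0, by = dt, length.out = length(x)), x, y,
                         valid = valid, interpolated = interpolated, dt = dt)
  structure(list(trajectory = traj, correct_door = correct_door,
                 session_type = "training", doors_active = doors_active,
                 T = T, censored = censored, events = NULL),
            class = "bc_trial")
}

# Clamped Gaussian random walk inside the focal compartment.
random_trial <- function(seed, n = 200, dt = 0.05, step_sd = 0.6,
                         correct_door = "lower") {
  set.seed(seed)
  x <- numeric(n); y <- numeric(n)
  x[1] <- runif(1, 0, 30); y[1] <- runif(1, 0, 30)
  for (i in 2:n) {
    x[i] <- min(30, max(0, x[i - 1] + rnorm(1, 0, step_sd)))
    y[i] <- min(30, max(0, y[i - 1] + rnorm(1, 0, step_sd)))
  }
  make_trial(x, y, dt = dt, correct_door = correct_door)
}

in_rect <- function(x, y, xmin, xmax, ymin, ymax)
  x >= xmin && x <= xmax && y >= ymin && y <= ymax

oracle_door_times <- function(trial, arena, dt = 0.05) {
  tr <- trial$trajectory
  keep <- if (!is.na(trial$T) && isFALSE(trial$censored))
    tr$t_s <= trial$T + 1e-9 else rep(TRUE, nrow(tr))
  s <- arena$trigger_zone_side
  doors <- arena$door_centers
  cd <- doors[trial$correct_door, ]
  id <- doors[setdiff(rownames(doors), trial$correct_door), ]
  nc <- ni <- 0
  for (i in which(keep)) {
    if (!tr$valid[i]) next
    if (in_rect(tr$x_cm[i], tr$y_cm[i], cd[1] - s, cd[1],
                cd[2] - s / 2, cd[2] + s / 2)) nc <- nc + 1
    if (in_rect(tr$x_cm[i], tr$y_cm[i], id[1] - s, id[1],
                id[2] - s / 2, id[2] + s / 2)) ni <- ni + 1
  }
  list(tau_C = nc * dt, tau_I = ni * dt,
       PI = if (nc + ni > 0) nc / (nc + ni) else NA_real_)
}

oracle_wall_times <- function(trial, arena, dt = 0.05) {
  tr <- trial$trajectory
  keep <- if (!is.na(trial$T) && isFALSE(trial$censored))
    tr$t_s <= trial$T + 1e-9 else rep(TRUE, nrow(tr))
  tw <- numeric(4)
  for (i in which(keep)) {
    if (!tr$valid[i]) next
    d <- c(arena$focal_len - tr$x_cm[i], tr$x_cm[i], tr$y_cm[i],
           arena$width - tr$y_cm[i])
    w <- which.min(d)   # which.min breaks ties by lowest index
    if (d[w] <= arena$wall_band) tw[w] <- tw[w] + dt
  }
  list(T_wall = tw, RI = if (sum(tw) > 0) tw[1] / sum(tw) else NA_real_)
}

oracle_entropy <- function(trial, arena, grid = 10) {
  tr <- trial$trajectory
  keep <- if (!is.na(trial$T) && isFALSE(trial$censored))
    tr$t_s <= trial$T + 1e-9 else rep(TRUE, nrow(tr))
  counts <- matrix(0, grid, grid)
  for (i in which(keep)) {
    if (!tr$valid[i]) next
    bx <- min(grid, max(1, ceiling(tr$x_cm[i] / (arena$focal_len / grid))))
    by <- min(grid, max(1, ceiling(tr$y_cm[i] / (arena$width / grid))))
    counts[bx, by] <- counts[bx, by] + 1
  }
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

oracle_heading <- function(trial, arena, dt = 0.05, floor = 0.5) {
  tr <- trial$trajectory
  keep <- if (!is.na(trial$T) && isFALSE(trial$censored))
    tr$t_s <= trial$T + 1e-9 else rep(TRUE, nrow(tr))
  n <- sum(keep)
  door <- arena$door_centers[trial$correct_door, ]
  vals <- c()
  for (i in seq_len(n - 1)) {
    h <- c(tr$x_cm[i + 1] - tr$x_cm[i], tr$y_cm[i + 1] - tr$y_cm[i])
    g <- c(door[1] - tr$x_cm[i], door[2] - tr$y_cm[i])
    if (sqrt(sum(h^2)) / dt < floor || sqrt(sum(g^2)) == 0) next
    if (tr$interpolated[i] || tr$interpolated[i + 1]) next
    if (!tr$valid[i] || !tr$valid[i + 1]) next
    cosang <- sum(h * g) / (sqrt(sum(h^2)) * sqrt(sum(g^2)))
    vals <- c(vals, acos(max(-1, min(1, cosang))) * 180 / pi)
  }
  if (length(vals)) mean(vals) else NA_real_
}

oracle_kinematics <- function(trial, dt = 0.05, floor = 0.5) {
  tr <- trial$trajectory
  keep <- if (!is.na(trial$T) && isFALSE(trial$censored))
    tr$t_s <= trial$T + 1e-9 else rep(TRUE, nrow(tr))
  n <- sum(keep)
  good <- !tr$interpolated & tr$valid
  vs <- as_ <- ws <- c()
  for (i in seq_len(n - 1)) {
    v1 <- c(tr$x_cm[i + 1] - tr$x_cm[i], tr$y_cm[i + 1] - tr$y_cm[i]) / dt
    if (good[i] && good[i + 1]) vs <- c(vs, sqrt(sum(v1^2)))
    if (i <= n - 2) {
      v2 <- c(tr$x_cm[i + 2] - tr$x_cm[i + 1],
              tr$y_cm[i + 2] - tr$y_cm[i + 1]) / dt
      if (good[i] && good[i + 1] && good[i + 2]) {
        as_ <- c(as_, sqrt(sum((v2 - v1)^2)) / dt)
        n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
        if (n1 >= floor && n2 >= floor) {
          cosang <- sum(v1 * v2) / (n1 * n2)
          ws <- c(ws, acos(max(-1, min(1, cosang))) / dt)
        }
      }
    }
  }
  list(v_mean = if (length(vs)) mean(vs) else NA_real_,
       a_mean = if (length(as_)) mean(as_) else NA_real_,
       omega_mean = if (length(ws)) mean(ws) else NA_real_)
}

oracle_freezing <- function(trial, dt = 0.05, window = 2, thresh = 4) {
  tr <- trial$trajectory
  keep <- if (!is.na(trial$T) && isFALSE(trial$censored))
    tr$t_s <= trial$T + 1e-9 else rep(TRUE, nrow(tr))
  n <- sum(keep)
  half <- round(window / 2 / dt)
  frozen <- 0
  for (i in seq_len(n)) {
    j0 <- max(1, i - half); j1 <- min(n, i + half)
    d <- sqrt((tr$x_cm[j1] - tr$x_cm[j0])^2 + (tr$y_cm[j1] - tr$y_cm[j0])^2)
    if (d < thresh) frozen <- frozen + 1
  }
  frozen * dt
}

oracle_thirds <- function(trial, arena) {
  tr <- trial$trajectory
  keep <- if (!is.na(trial$T) && isFALSE(trial$censored))
    tr$t_s <= trial$T + 1e-9 else rep(TRUE, nrow(tr))
  hits <- tot <- 0
  for (i in which(keep)) {
    if (!tr$valid[i]) next
    tot <- tot + 1
    if (tr$y_cm[i] >= arena$width / 3 && tr$y_cm[i] <= 2 * arena$width / 3)
      hits <- hits + 1
  }
  if (tot) hits / tot else NA_real_
}

# Brute-force trigger rule: scan every trailing window.
oracle_trigger <- function(presence, dt = 0.05, window_s = 5,
                           required_s = 3) {
  w <- round(window_s / dt); need <- round(required_s / dt)
  for (i in seq_along(presence)) {
    lo <- max(1, i - w + 1)
    if (sum(presence[lo:i]) >= need) return(i * dt)
  }
  NA_real_
}

# Distance from a point to a segment (for the nearest-wall oracle).
seg_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- max(0, min(1, t))
  sqrt(sum((a + t * ab - p)^2))
}
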