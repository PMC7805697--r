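#' Counterbalanced cohort design
#'
#' Builds the session table of the full study: `n_subjects` subjects split
#' equally between the individual and social training conditions, each
#' condition run in two batches, with the correct door fully counterbalanced
#' across conditions, batches, and subjects.  Each subject performs
#' `n_trials` training trials plus doors-closed test sessions before the
#' first trial and after trials 10 and 20 (configurable).  Sex is assigned at
#' a 5:4 female:male ratio within each batch.
#'
#' Learning is injected as a linear growth of the attraction gain toward the
#' correct door: at training trial k the gain is
#' `min(1, pref_drift * k + social_boost * k)` in the social condition
#' (without the `social_boost` term in the individual condition); test
#' sessions use the gain implied by the number of completed trials.
#' `side_bias` adds a constant lateral attraction toward the preferred side
#' of the tank, emulating the uncontrolled environmental bias the analysis
#' encodes as the correct-door-location factor.
#'
#' @param n_subjects Number of subjects (divisible by 4; default 36).
#' @param n_trials Training trials per subject (default 20).
#' @param test_sessions Completed-trial counts at which doors-closed tests
#'   run (default `c(0, 10, 20)`).
#' @param pref_drift Attraction-gain growth per training trial.
#' @param social_boost Additional per-trial gain in the social condition.
#' @param side_bias Constant lateral attraction gain toward `preferred_side`.
#' @param preferred_side `"lower"` (y = 0) or `"upper"` (y = width).
#' @param release_duration Release-phase duration of training trials (s);
#'   default 1800 (the 30 min limit).
#' @param test_release_duration Release-phase duration of test sessions (s);
#'   default 600.
#' @param seed Master seed; per-session child seeds are derived from it.
#' @return A `bc_design`: list of the above parameters plus `$sessions`, a
#'   data frame with one row per subject x session carrying all labels and
#'   the derived child seed.
#' @examples
#' d <- cohort_design(seed = 1)
#' table(d$sessions$condition, d$sessions$session_type)
#' @export
cohort_design <- function(n_subjects = 36, n_trials = 20,
                          test_sessions = c(0, 10, 20),
                          pref_drift = 0.02, social_boost = 0,
                          side_bias = 0.1,
                          preferred_side = c("lower", "upper"),
                          release_duration = 1800,
                          test_release_duration = 600,
                          seed = 1) {
  preferred_side <- match.arg(preferred_side)
  if (n_subjects %% 4 != 0)
    stop("n_subjects must be divisible by 4 (2 conditions x 2 batches)")
  per_batch <- n_subjects / 4
  subjects <- data.frame(
    subject = seq_len(n_subjects),
    condition = rep(c("individual", "social"), each = n_subjects / 2),
    batch = rep(rep(1:2, each = per_batch), 2)
  )
  # Alternate the correct door within each batch, flipping the starting door
  # between batches so the assignment is counterbalanced overall even with an
  # odd batch size.
  subjects$correct_door <- unlist(lapply(seq_len(4), function(b) {
    start <- if (b %% 2 == 1) 0 else 1
    c("lower", "upper")[(seq_len(per_batch) + start) %% 2 + 1]
  }))
  n_f <- ceiling(5 * per_batch / 9)  # 5:4 female:male per batch of 9
  subjects$sex <- unlist(lapply(seq_len(4), function(b)
    rep(c("F", "M"), c(n_f, per_batch - n_f))))
  subjects$door_location <- ifelse(subjects$correct_door == preferred_side,
                                   "preferred", "nonpreferred")

  one_subject <- function(s) {
    trials <- seq_len(n_trials)
    rows <- list()
    sidx <- 0
    emit <- function(type, trial, test) {
      sidx <<- sidx + 1
      data.frame(subject = s, session_index = sidx, session_type = type,
                 trial = trial, test = test)
    }
    for (k in 0:n_trials) {
      if (k %in% test_sessions) rows[[length(rows) + 1]] <- emit("test", NA, k)
      if (k < n_trials) rows[[length(rows) + 1]] <- emit("training", k + 1, NA)
    }
    do.call(rbind, rows)
  }
  sess <- do.call(rbind, lapply(seq_len(n_subjects), one_subject))
  sess <- merge(sess, subjects, by = "subject", sort = FALSE)
  sess <- sess[order(sess$subject, sess$session_index), ]
  rownames(sess) <- NULL
  completed <- ifelse(sess$session_type == "test", sess$test, sess$trial)
  boost <- ifelse(sess$condition == "social", social_boost, 0)
  sess$attraction_gain <- pmin(1, (pref_drift + boost) * completed)
  sess$seed <- derive_seed(seed, sess$subject, sess$session_index)
  structure(list(n_subjects = n_subjects, n_trials = n_trials,
                 test_sessions = test_sessions, pref_drift = pref_drift,
                 social_boost = social_boost, side_bias = side_bias,
                 preferred_side = preferred_side,
                 release_duration = release_duration,
                 test_release_duration = test_release_duration,
                 seed = seed, sessions = sess),
            class = "bc_design")
}

# Deterministic child seed in [1, 2^31 - 2] from (master, subject, session).
derive_seed <- function(master, subject, session) {
  m <- 2147483647
  h <- (as.numeric(master) %% m)
  h <- (h * 48271 + as.numeric(subject) * 69621 +
          as.numeric(session) * 16807) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Simulate one session of the cohort
#'
#' Simulates the release-phase trajectory for one row of the design's session
#' table: the subject is released at the cylinder centre and swims confined
#' to the focal compartment, with attraction toward the correct door's
#' trigger zone at the gain the design prescribes for that session, plus the
#' design's constant side bias.
#'
#' @param design A `bc_design`.
#' @param i Row index into `design$sessions`.
#' @param params A [swim_params()] object (its `attraction_gain` is
#'   overridden per session).
#' @param arena A `bc_arena`.
#' @return A `bc_trial` record: list with `trajectory`, all design labels,
#'   `doors_active` (FALSE for test sessions), and `release_duration`.
#'   Door events and the trigger time `T` are filled by
#'   [run_trial_session()].
#' @export
simulate_trial <- function(design, i, params, arena) {
  row <- design$sessions[i, ]
  is_test <- row$session_type == "test"
  duration <- if (is_test) design$test_release_duration else
    design$release_duration
  p <- params
  p$attraction_gain <- row$attraction_gain
  zc <- trigger_zone(arena, row$correct_door)
  target <- c((zc$xmin + zc$xmax) / 2, (zc$ymin + zc$ymax) / 2)
  side_y <- if (design$preferred_side == "lower") 0 else arena$width
  traj <- simulate_trajectory(
    p, arena, duration = duration, start = arena$cylinder_center,
    attraction_point = target, side_bias = design$side_bias,
    side_y = side_y, bounds = c(0, arena$focal_len, 0, arena$width),
    seed = row$seed)
  structure(list(trajectory = traj,
                 subject = row$subject, condition = row$condition,
                 batch = row$batch, sex = row$sex,
                 correct_door = row$correct_door,
                 door_location = row$door_location,
                 session_type = row$session_type,
                 trial = row$trial, test = row$test,
                 session_index = row$session_index,
                 release_duration = duration,
                 doors_active = !is_test,
                 T = NA_real_, censored = NA, events = NULL),
            class = "bc_trial")
}

#' Simulate the whole cohort
#'
#' Runs [simulate_trial()] for every row of the design's session table.  At
#' the default full scale (36 subjects x 23 sessions x 30 min at 20 Hz) the
#' returned list holds ~30 million samples; for statistical simulation
#' studies use a reduced design or the streaming runner
#' [run_virtual_experiment()], which discards trajectories after scoring.
#'
#' @inheritParams simulate_trial
#' @param session_type Optional filter: `"training"`, `"test"`, or `NULL`
#'   (all sessions).
#' @return List of `bc_trial` records.
#' @export
simulate_cohort <- function(design, params, arena, session_type = NULL) {
  idx <- seq_len(nrow(design$sessions))
  if (!is.null(session_type))
    idx <- idx[design$sessions$session_type == session_type]
  lapply(idx, function(i) simulate_trial(design, i, params, arena))
}
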