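#' Default experiment configuration
#'
#' A nested list that serializes losslessly to/from JSON and fully
#' determines a virtual experiment: arena overrides, swimming parameters,
#' cohort design, tracker configuration, metric options, statistics
#' options, and the master seed (which determines every child seed).
#'
#' @param seed Master seed.
#' @return A `bc_config` list with elements `arena`, `swim`, `design`,
#'   `tracker`, `metrics`, `stats`, `seed`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    arena = list(),
    swim = unclass(swim_params()),
    design = list(n_subjects = 36, n_trials = 20,
                  test_sessions = c(0, 10, 20),
                  pref_drift = 0.02, social_boost = 0, side_bias = 0.1,
                  preferred_side = "lower",
                  release_duration = 1800, test_release_duration = 600),
    tracker = unclass(tracker_config()),
    metrics = unclass(metric_options()),
    stats = list(nominal = 0.050, n_tests = 3, prune_p = 0.05),
    seed = seed), class = "bc_config")
}

#' Read / write an experiment config as JSON
#'
#' @param path JSON file path.
#' @param cfg A `bc_config`.
#' @return `load_config` returns a `bc_config`; `save_config` returns
#'   `path` invisibly.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (k in names(raw)) {
    if (is.list(cfg[[k]]) && is.list(raw[[k]])) {
      for (kk in names(raw[[k]])) cfg[[k]][[kk]] <- raw[[k]][[kk]]
    } else cfg[[k]] <- raw[[k]]
  }
  cfg
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

config_objects <- function(cfg) {
  list(arena = arena_from_list(cfg$arena),
       params = do.call(swim_params, cfg$swim),
       design = do.call(cohort_design, c(cfg$design, list(seed = cfg$seed))),
       tracker = do.call(tracker_config, cfg$tracker),
       opts = do.call(metric_options, cfg$metrics))
}

#' Run the end-to-end virtual experiment
#'
#' Simulates the whole counterbalanced cohort trial by trial, runs the
#' session state machine (trigger rule, censoring) on each release-phase
#' trajectory, scores every behavioral measure, and runs the statistical
#' stage.  Trials are processed in a stream: each trajectory is discarded
#' after scoring, so the full-scale study fits in modest memory.
#'
#' In `"tracked"` mode each trial is additionally rendered to synthetic
#' frames and re-tracked by the frame-differencing tracker, and the tracked
#' trajectory (not the ground truth) is scored — useful to validate the
#' vision stage, but far slower; `"ground-truth"` is the default for
#' statistical experiments.
#'
#' @param cfg A `bc_config` (see [default_config()]).
#' @param out_dir Optional output directory; if given, writes
#'   `metrics.csv`, `report.json`, `config.json`, and `manifest.json`
#'   (config hash, seed, package version).
#' @param mode `"ground-truth"` or `"tracked"`.
#' @param tracked_resolution Frame resolution for tracked mode.
#' @param progress Print a line per subject.
#' @return List with `metrics` (data frame, one row per session), `report`
#'   (a `bc_report`), `design`, and `manifest`.
#' @export
run_virtual_experiment <- function(cfg = default_config(), out_dir = NULL,
                                   mode = c("ground-truth", "tracked"),
                                   tracked_resolution = c(320, 320),
                                   progress = FALSE) {
  mode <- match.arg(mode)
  obj <- config_objects(cfg)
  arena <- obj$arena
  design <- obj$design
  time_limit <- design$release_duration
  rows <- vector("list", nrow(design$sessions))
  for (i in seq_len(nrow(design$sessions))) {
    trial <- simulate_trial(design, i, obj$params, arena)
    if (mode == "tracked") {
      trial <- retrack_trial(trial, arena, obj$tracker, tracked_resolution)
    }
    trial <- run_trial_session(trial, arena, time_limit = time_limit)
    rows[[i]] <- trial_metrics(trial, arena, obj$opts)
    if (progress && design$sessions$session_index[i] == 1)
      message("subject ", design$sessions$subject[i])
  }
  metrics <- do.call(rbind, rows)
  report <- summarize_study(
    metrics[metrics$session_type == "training", ],
    metrics[metrics$session_type == "test", ],
    nominal = cfg$stats$nominal, n_tests = cfg$stats$n_tests,
    prune_p = cfg$stats$prune_p)
  manifest <- list(package = "roboshoal",
                   version = as.character(packageVersion("roboshoal")),
                   seed = cfg$seed, mode = mode,
                   config_hash = digest::digest(unclass(cfg)),
                   n_sessions = nrow(metrics))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_metrics_csv(metrics, file.path(out_dir, "metrics.csv"))
    write_report_json(report, file.path(out_dir, "report.json"))
    save_config(cfg, file.path(out_dir, "config.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(metrics = metrics, report = report, design = design,
       manifest = manifest)
}

# Render a trial's trajectory to frames and replace it by the tracked one.
retrack_trial <- function(trial, arena, tracker, resolution) {
  frames <- render_frames(trial$trajectory, arena, resolution = resolution, wobble_amp = 0.15,
                          region = c(0, arena$focal_len, 0, arena$width))
  tracked <- track_video(frames, cfg = tracker)$subject
  trial$trajectory <- tracked
  trial
}

#' Trajectory CSV I/O
#'
#' The on-disk dialect: header `t_s,x_cm,y_cm,identity,valid,interpolated`,
#' decimal point, UTF-8; times on a strictly increasing uniform grid.
#' Writing and re-reading is the identity up to 6-significant-digit float
#' formatting; malformed files are rejected with the offending line.
#'
#' @param traj A `bc_trajectory`.
#' @param path File path.
#' @param dt Expected grid step (s); default 0.05.
#' @param arena Optional `bc_arena` for coordinate bounds validation.
#' @return `read_trajectory_csv` returns a `bc_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- traj
  out$t_s <- signif(out$t_s, 6)
  out$x_cm <- signif(out$x_cm, 6)
  out$y_cm <- signif(out$y_cm, 6)
  write.csv(as.data.frame(out), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path, dt = 0.05, arena = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "x_cm", "y_cm", "identity", "valid", "interpolated")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  if (!nrow(d)) stop("empty trajectory file: ", path)
  for (col in c("t_s", "x_cm", "y_cm"))
    if (!is.numeric(d[[col]]))
      stop("non-numeric values in column ", col)
  steps <- diff(d$t_s)
  bad <- which(abs(steps - dt) > 1e-6)
  if (length(bad))
    stop(sprintf("time step %.6g s at data row %d differs from %.6g s",
                 steps[bad[1]], bad[1] + 1, dt))
  if (!is.null(arena)) {
    oob <- which(d$x_cm < 0 | d$x_cm > arena$length |
                   d$y_cm < 0 | d$y_cm > arena$width)
    if (length(oob))
      stop(sprintf("coordinates out of tank bounds at data row %d", oob[1]))
  }
  new_trajectory(d$t_s, d$x_cm, d$y_cm, identity = d$identity,
                 valid = as.logical(d$valid),
                 interpolated = as.logical(d$interpolated), dt = dt)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (one trajectory to CSV), `demo-schedule` (replica
#' schedule to CSV), `score` (trajectory CSV to metrics CSV), `analyze`
#' (metrics CSV to report JSON), `run-experiment` (full virtual
#' experiment).  Invoke via `Rscript -e 'roboshoal::bc_cli()' <cmd> ...` or
#' the installed `inst/cli/roboshoal` script.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Exit status, invisibly.
#' @export
bc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: roboshoal <simulate|demo-schedule|score|analyze|",
            "run-experiment> [--config F] [--seed N] [--out F] ",
            "[--in F] [--door lower|upper] [--duration S] ",
            "[--mode ground-truth|tracked]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--out", type = "character", default = NULL),
      optparse::make_option("--in", type = "character", default = NULL,
                            dest = "input"),
      optparse::make_option("--door", type = "character",
                            default = "lower"),
      optparse::make_option("--duration", type = "double", default = 600),
      optparse::make_option("--mode", type = "character",
                            default = "ground-truth"))),
    args = args[-1])
  cfg <- if (!is.null(opts$config)) load_config(opts$config) else
    default_config(seed = opts$seed)
  cfg$seed <- opts$seed
  obj <- config_objects(cfg)
  switch(cmd,
    "simulate" = {
      traj <- simulate_trajectory(obj$params, obj$arena,
                                  duration = opts$duration,
                                  start = obj$arena$cylinder_center,
                                  seed = opts$seed)
      write_trajectory_csv(traj, opts$out %||% "trajectory.csv")
    },
    "demo-schedule" = {
      sched <- build_demo_schedule(obj$arena, opts$door)
      write_schedule_csv(sched, opts$out %||% "schedule.csv")
    },
    "score" = {
      traj <- read_trajectory_csv(opts$input, dt = obj$params$dt,
                                  arena = obj$arena)
      trial <- run_trial_session(traj, obj$arena, correct_door = opts$door,
                                 time_limit = max(traj$t_s))
      write_metrics_csv(trial_metrics(trial, obj$arena, obj$opts),
                        opts$out %||% "metrics.csv")
    },
    "analyze" = {
      m <- read_metrics_csv(opts$input)
      rep <- summarize_study(m[m$session_type == "training", ],
                             m[m$session_type == "test", ],
                             nominal = cfg$stats$nominal,
                             n_tests = cfg$stats$n_tests,
                             prune_p = cfg$stats$prune_p)
      write_report_json(rep, opts$out %||% "report.json")
    },
    "run-experiment" = {
      run_virtual_experiment(cfg, out_dir = opts$out %||% "experiment_out",
                             mode = opts$mode)
    },
    stop("unknown command: ", cmd))
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
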