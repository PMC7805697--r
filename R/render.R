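#' Render synthetic camera frames from trajectories
#'
#' Produces 8-bit grayscale frames (integer matrices, 0-255, row 1 = top of
#' image) emulating the overhead tracking camera: white background with a
#' dark fish-shaped blob (an ellipse with major axis one body length,
#' oriented along the direction of motion) at each valid trajectory sample.
#' The affine cm-to-pixel calibration is returned so tracker output can be
#' compared against ground truth.
#'
#' @param trajs A `bc_trajectory` or list of them sharing one time grid.
#' @param arena A `bc_arena`.
#' @param resolution `c(width_px, height_px)`; default `c(640, 480)`.
#' @param region View bounds `c(xmin, xmax, ymin, ymax)` in cm; default the
#'   full tank.  Use the focal compartment for tracker fixtures.
#' @param noise_sd Optional Gaussian pixel noise SD (gray levels).
#' @param blob_value Gray level of the fish body (default 40).
#' @param aspect Minor/major axis ratio of the body ellipse (default 1/3).
#' @param wobble_amp Body-undulation emulation: the silhouette alternately
#'   dilates and contracts by this relative amount on successive frames, so
#'   the frame difference of even a slowly coasting fish is a closed
#'   outline ring that hole-filling restores to a solid, centred blob —
#'   the mechanism the live frame-differencing tracker relies on with real,
#'   continuously undulating fish.  With `wobble_amp = 0` (the default) a
#'   stationary fish renders identical consecutive frames and is only
#'   trackable through the Kalman predictor.  Tracker validation fixtures
#'   should use a non-zero amplitude (e.g. 0.15).
#' @return A `bc_frames` list: `frames` (list of integer matrices), `t_s`,
#'   `calib` (see [cm_to_px()]), and `ground_truth` (list of n x 2 cm
#'   position matrices, one per trajectory).
#' @export
render_frames <- function(trajs, arena, resolution = c(640, 480),
                          region = NULL, noise_sd = 0, blob_value = 40,
                          aspect = 1 / 3, wobble_amp = 0) {
  if (inherits(trajs, "bc_trajectory")) trajs <- list(trajs)
  if (is.null(region)) region <- c(0, arena$length, 0, arena$width)
  t0 <- trajs[[1]]$t_s
  for (tr in trajs)
    if (length(tr$t_s) != length(t0) || any(abs(tr$t_s - t0) > 1e-9))
      stop("trajectories must share a time grid")
  w_px <- resolution[1]; h_px <- resolution[2]
  s <- min(w_px / (region[2] - region[1]), h_px / (region[4] - region[3]))
  bl_px <- arena$body_length * s
  if (bl_px < 2)
    stop(sprintf("resolution too low: body length is %.2f px (< 2 px)",
                 bl_px))
  calib <- list(px_per_cm = s, region = region,
                width_px = w_px, height_px = h_px)
  a <- arena$body_length / 2            # ellipse semi-major (cm)
  b <- a * aspect                       # semi-minor (cm)
  headings <- lapply(trajs, function(tr) {
    dx <- diff(tr$x_cm); dy <- diff(tr$y_cm)
    h <- atan2(dy, dx)
    h <- c(h, h[length(h)])
    # carry the last moving heading through stationary stretches
    still <- c(sqrt(dx^2 + dy^2) < 1e-9, FALSE)
    for (i in seq_along(h)) if (i > 1 && still[i]) h[i] <- h[i - 1]
    h
  })
  n <- length(t0)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    f <- matrix(255L, nrow = h_px, ncol = w_px)
    for (k in seq_along(trajs)) {
      tr <- trajs[[k]]
      if (!tr$valid[i]) next
      s_i <- wobble_amp * (-1)^(i + k)
      # sides swing more than the ends, like a tail sweep, so the frame
      # difference forms a closed ring all around the silhouette
      f <- draw_ellipse(f, tr$x_cm[i], tr$y_cm[i], headings[[k]][i],
                        a * (1 + s_i), b * (1 + 3 * s_i), calib, blob_value)
    }
    if (noise_sd > 0) {
      f <- f + matrix(as.integer(round(rnorm(length(f), 0, noise_sd))),
                      nrow = h_px)
      f[f < 0L] <- 0L; f[f > 255L] <- 255L
    }
    frames[[i]] <- f
  }
  structure(list(frames = frames, t_s = t0, calib = calib,
                 ground_truth = lapply(trajs, function(tr)
                   cbind(x = tr$x_cm, y = tr$y_cm))),
            class = "bc_frames")
}

draw_ellipse <- function(f, x, y, heading, a, b, calib, value) {
  px <- cm_to_px(cbind(x, y), calib)
  r_px <- a * calib$px_per_cm + 1
  cols <- max(1, floor(px[1] - r_px)):min(calib$width_px, ceiling(px[1] + r_px))
  rows <- max(1, floor(px[2] - r_px)):min(calib$height_px, ceiling(px[2] + r_px))
  if (!length(cols) || !length(rows)) return(f)
  cc <- matrix(cols, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  rr <- matrix(rows, nrow = length(rows), ncol = length(cols))
  pts <- px_to_cm(cbind(as.vector(cc), as.vector(rr)), calib)
  u <- (pts[, 1] - x) * cos(heading) + (pts[, 2] - y) * sin(heading)
  v <- -(pts[, 1] - x) * sin(heading) + (pts[, 2] - y) * cos(heading)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- cbind(as.vector(rr)[inside], as.vector(cc)[inside])
  f[idx] <- as.integer(value)
  f
}

#' Calibration transforms between arena cm and image pixels
#'
#' Pixel coordinates are `(col, row)` with row 1 at the top of the image;
#' arena y increases upward, so the row axis is flipped.  The pixel centre of
#' `(col, row) = (1, 1)` corresponds to the top-left of the viewed region.
#'
#' @param p n x 2 matrix: cm points for `cm_to_px`, `(col, row)` pixel points
#'   for `px_to_cm`.
#' @param calib Calibration list from [render_frames()] (fields `px_per_cm`,
#'   `region`, `width_px`, `height_px`).
#' @return n x 2 matrix in the other coordinate system.
#' @export
cm_to_px <- function(p, calib) {
  p <- as_points(p)
  cbind(col = (p[, 1] - calib$region[1]) * calib$px_per_cm + 0.5,
        row = (calib$region[4] - p[, 2]) * calib$px_per_cm + 0.5)
}

#' @rdname cm_to_px
#' @export
px_to_cm <- function(p, calib) {
  p <- as_points(p)
  cbind(x = (p[, 1] - 0.5) / calib$px_per_cm + calib$region[1],
        y = calib$region[4] - (p[, 2] - 0.5) / calib$px_per_cm)
}

#' Write / read a frame sequence as numbered PNG files
#'
#' Frames are written as `frame_000001.png`, ... with a JSON sidecar
#' `calibration.json` holding the cm-to-pixel transform and the time grid.
#'
#' @param frames A `bc_frames` object.
#' @param dir Output directory (created if needed).
#' @return `write_frames_png` returns `dir`; `read_frames_png` returns a
#'   `bc_frames` object (without ground truth).
#' @export
write_frames_png <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames$frames)) {
    png::writePNG(frames$frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  jsonlite::write_json(list(calib = frames$calib, t_s = frames$t_s),
                       file.path(dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_frames_png
#' @export
read_frames_png <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "calibration.json"),
                              simplifyVector = TRUE)
  meta$calib$region <- as.numeric(meta$calib$region)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no frames found in ", dir)
  frames <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    matrix(as.integer(round(m * 255)), nrow = nrow(m))
  })
  structure(list(frames = frames, t_s = as.numeric(meta$t_s),
                 calib = meta$calib, ground_truth = NULL),
            class = "bc_frames")
}
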