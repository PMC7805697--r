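#' Experimental arena geometry
#'
#' Builds the geometry of the learning tank: a 74 x 30 cm tank divided into a
#' focal compartment (30 cm, where the subject swims and is tracked), a middle
#' compartment (34 cm), and a stimulus compartment (10 cm) holding the
#' conspecific shoal behind one-way glass.  The partition between the focal
#' and middle compartments carries two doors, each 1.5 body lengths wide,
#' centred at 1/4 and 3/4 of the tank width.  A 2 x 2 body-length unmarked
#' trigger zone lies in front of each door on the focal side.
#'
#' Coordinate frame: origin at the focal-compartment corner, x increasing
#' along the 74 cm axis toward the stimulus compartment, y across the 30 cm
#' width.  All lengths in cm, times in s.
#'
#' @param length,width Tank dimensions in cm.
#' @param focal_len,middle_len,stimulus_len Compartment lengths (cm); must sum
#'   to `length`.
#' @param body_length Nominal subject body length (BL) in cm; door width is
#'   1.5 BL and the trigger zone side is 2 BL.
#' @param cylinder_diameter Diameter (cm) of the transparent confinement
#'   cylinder at the centre of the focal compartment.
#' @param wall_band Width (cm) of the wall-proximity bands used by the reward
#'   index (time within `wall_band` of each focal-compartment wall).
#' @param depth Water depth in cm (metadata only; the model is 2D).
#' @return An object of class `bc_arena`: a list with the tank dimensions,
#'   door centers (`door_centers`, rows `lower`/`upper`), `door_width`,
#'   `trigger_zone_side`, `wall_band`, `cylinder_center`,
#'   `cylinder_diameter`, and `body_length`.
#' @examples
#' arena <- make_default_arena()
#' arena$door_centers          # (30, 7.5) and (30, 22.5)
#' arena$trigger_zone_side     # 6 cm = 2 BL
#' @export
make_default_arena <- function(length = 74, width = 30,
                               focal_len = 30, middle_len = 34,
                               stimulus_len = 10, body_length = 3,
                               cylinder_diameter = 8, wall_band = 3,
                               depth = 30) {
  if (abs(focal_len + middle_len + stimulus_len - length) > 1e-9)
    stop("compartment lengths must sum to the tank length")
  if (width <= 0 || length <= 0 || body_length <= 0)
    stop("dimensions must be positive")
  arena <- structure(list(
    length = length, width = width,
    focal_len = focal_len, middle_len = middle_len,
    stimulus_len = stimulus_len,
    body_length = body_length,
    door_width = 1.5 * body_length,
    door_centers = matrix(c(focal_len, width / 4,
                            focal_len, 3 * width / 4),
                          nrow = 2, byrow = TRUE,
                          dimnames = list(c("lower", "upper"), c("x", "y"))),
    trigger_zone_side = 2 * body_length,
    wall_band = wall_band,
    cylinder_center = c(focal_len / 2, width / 2),
    cylinder_diameter = cylinder_diameter,
    depth = depth
  ), class = "bc_arena")
  arena
}

#' @export
print.bc_arena <- function(x, ...) {
  cat(sprintf("<bc_arena> %g x %g cm tank; compartments %g/%g/%g cm\n",
              x$length, x$width, x$focal_len, x$middle_len, x$stimulus_len))
  cat(sprintf("  doors (%.1f cm wide) at (%g, %g) and (%g, %g); trigger zone %g x %g cm\n",
              x$door_width,
              x$door_centers[1, 1], x$door_centers[1, 2],
              x$door_centers[2, 1], x$door_centers[2, 2],
              x$trigger_zone_side, x$trigger_zone_side))
  invisible(x)
}

#' Build an arena from a (possibly partial) list of overrides
#'
#' Used when deserializing the `arena` key of a JSON experiment config.
#'
#' @param overrides Named list of arguments to [make_default_arena()].
#' @return A `bc_arena`.
#' @export
arena_from_list <- function(overrides = list()) {
  keep <- intersect(names(overrides), names(formals(make_default_arena)))
  do.call(make_default_arena, overrides[keep])
}

#' Zone constructors
#'
#' Zones are axis-aligned rectangles in arena coordinates with a boundary-
#' inclusive membership convention.
#'
#' * `trigger_zone()`: the square (side 2 BL) in front of a door on the focal
#'   side of the partition, centred on the door's y position.
#' * `wall_band_zone()`: the band within `arena$wall_band` cm of one of the
#'   four focal-compartment walls.  Wall 1 is the door partition (the wall
#'   nearest the conspecifics), wall 2 the opposite end wall, wall 3 the
#'   y = 0 side wall, wall 4 the y = width side wall.
#' * `width_third_zone()`: one of three equal-area rectangles along the tank
#'   width (`"lower"`, `"middle"`, `"upper"`).
#' * `compartment_zone()`: a full compartment (`"focal"`, `"middle"`,
#'   `"stimulus"`).
#'
#' @param arena A `bc_arena`.
#' @param door `"lower"` or `"upper"`.
#' @param wall Wall index 1-4.
#' @param which Third or compartment name.
#' @return A `bc_zone`: list with `kind` and bounds `xmin`, `xmax`, `ymin`,
#'   `ymax`.
#' @name zones
#' @examples
#' arena <- make_default_arena()
#' z <- trigger_zone(arena, "lower")
#' zone_contains(z, c(28, 7.5), arena)   # TRUE
#' @export
trigger_zone <- function(arena, door = c("lower", "upper")) {
  door <- match.arg(door)
  ctr <- arena$door_centers[door, ]
  s <- arena$trigger_zone_side
  new_zone("trigger_zone", ctr["x"] - s, ctr["x"], ctr["y"] - s / 2,
           ctr["y"] + s / 2, door = door)
}

#' @rdname zones
#' @export
wall_band_zone <- function(arena, wall) {
  stopifnot(wall %in% 1:4)
  b <- arena$wall_band
  fl <- arena$focal_len
  w <- arena$width
  bounds <- switch(wall,
    list(fl - b, fl, 0, w),   # 1: door partition
    list(0, b, 0, w),         # 2: end wall opposite the partition
    list(0, fl, 0, b),        # 3: y = 0 side wall
    list(0, fl, w - b, w))    # 4: y = width side wall
  new_zone("wall_band", bounds[[1]], bounds[[2]], bounds[[3]], bounds[[4]],
           wall = wall)
}

#' @rdname zones
#' @export
width_third_zone <- function(arena, which = c("lower", "middle", "upper")) {
  which <- match.arg(which)
  i <- match(which, c("lower", "middle", "upper"))
  h <- arena$width / 3
  new_zone("width_third", 0, arena$length, (i - 1) * h, i * h, third = which)
}

#' @rdname zones
#' @export
compartment_zone <- function(arena, which = c("focal", "middle", "stimulus")) {
  which <- match.arg(which)
  xr <- switch(which,
    focal = c(0, arena$focal_len),
    middle = c(arena$focal_len, arena$focal_len + arena$middle_len),
    stimulus = c(arena$focal_len + arena$middle_len, arena$length))
  new_zone("compartment", xr[1], xr[2], 0, arena$width, compartment = which)
}

new_zone <- function(kind, xmin, xmax, ymin, ymax, ...) {
  structure(list(kind = kind, xmin = unname(xmin), xmax = unname(xmax),
                 ymin = unname(ymin), ymax = unname(ymax), ...),
            class = "bc_zone")
}

#' Zone membership predicate
#'
#' Boundary points count as inside.  Points outside the tank raise an error
#' (they indicate an invalid trajectory sample).
#'
#' @param zone A `bc_zone`.
#' @param p A length-2 point `c(x, y)` or an n x 2 matrix of points (cm).
#' @param arena Optional `bc_arena`; when supplied, points outside the tank
#'   bounds are rejected.
#' @return Logical vector of memberships.
#' @export
zone_contains <- function(zone, p, arena = NULL) {
  p <- as_points(p)
  if (!is.null(arena)) {
    bad <- p[, 1] < 0 | p[, 1] > arena$length | p[, 2] < 0 | p[, 2] > arena$width
    if (any(bad))
      stop(sprintf("point outside tank bounds (first offending index %d)",
                   which(bad)[1]))
  }
  p[, 1] >= zone$xmin & p[, 1] <= zone$xmax &
    p[, 2] >= zone$ymin & p[, 2] <= zone$ymax
}

as_points <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 2) stop("a point must have two coordinates")
    p <- matrix(p, ncol = 2)
  }
  p <- as.matrix(p)
  if (ncol(p) != 2) stop("points must be an n x 2 matrix")
  storage.mode(p) <- "double"
  p
}

#' Nearest focal-compartment wall
#'
#' For points inside the focal compartment, returns the index of the nearest
#' of its four bounding walls and the distance to it.  Wall 1 is the door
#' partition (x = `focal_len`), wall 2 the opposite end wall (x = 0), wall 3
#' the y = 0 side wall, wall 4 the y = width side wall.  Ties are broken by
#' the lowest index.
#'
#' @param arena A `bc_arena`.
#' @param p Point or n x 2 matrix of points inside the focal compartment.
#' @return A list with integer vector `wall` and numeric vector `distance`.
#' @examples
#' arena <- make_default_arena()
#' nearest_wall(arena, c(29, 15))  # wall 1, distance 1
#' @export
nearest_wall <- function(arena, p) {
  p <- as_points(p)
  if (any(p[, 1] < 0 | p[, 1] > arena$focal_len |
          p[, 2] < 0 | p[, 2] > arena$width))
    stop("nearest_wall() expects points inside the focal compartment")
  d <- cbind(arena$focal_len - p[, 1],  # wall 1: partition
             p[, 1],                    # wall 2: x = 0
             p[, 2],                    # wall 3: y = 0
             arena$width - p[, 2])      # wall 4: y = width
  wall <- max.col(-d, ties.method = "first")
  list(wall = wall, distance = d[cbind(seq_len(nrow(d)), wall)])
}
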