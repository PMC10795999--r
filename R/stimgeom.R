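# Looming-trajectory geometry: world-to-screen projection, angular size,
# time-to-collision, centre-of-mass alignment, trial schedules and rendered
# frame sequences.

#' Full angular diameter of a sphere at a viewing distance
#'
#' The visual angle subtended by a sphere of physical diameter
#' `sphere_diameter` seen from `distance`, computed with the exact pinhole
#' relation `2 * atan((d/2) / D)`.
#'
#' @param sphere_diameter Sphere diameter in metres.
#' @param distance Viewing distance in metres.
#' @return Angular diameter in degrees.
#' @examples
#' angular_diameter(0.06, 2.75)   # ~1.25 deg
#' @export
angular_diameter <- function(sphere_diameter, distance) {
  if (any(sphere_diameter <= 0)) stop_domain("`sphere_diameter` must be > 0")
  if (any(distance <= 0)) stop_domain("`distance` must be > 0")
  rad2deg(2 * atan((sphere_diameter / 2) / distance))
}

#' Time to collision in milliseconds
#'
#' Remaining approach distance divided by speed, in integer milliseconds
#' (rounded half away from zero, matching how stimulus timings are reported).
#'
#' @param distance Remaining distance in metres (>= 0).
#' @param speed Approach speed in metres/second (> 0).
#' @return Time-to-collision in whole milliseconds.
#' @examples
#' time_to_collision(3.3, 24)    # 138
#' time_to_collision(2.75, 24)   # 115
#' @export
time_to_collision <- function(distance, speed) {
  if (any(speed <= 0)) stop_domain("`speed` must be > 0")
  if (any(distance < 0)) stop_domain("`distance` must be >= 0")
  round_half_away(1000 * distance / speed)
}

#' Specification of one looming/receding trajectory
#'
#' Bundles the 3D geometry of a single trial: the object starts at
#' `start_distance` with the given lateral/vertical offsets (placed in
#' `quadrant`; +x rightward, +y upward) and travels in a straight line
#' towards its would-be impact point (`impact_lateral_offset` from the
#' nasion, at distance 0), disappearing at `end_distance`.
#'
#' @param start_distance,end_distance Viewing-axis distances in metres. For
#'   `direction = "approach"` requires `start_distance > end_distance >= 0`;
#'   reversed for `"recede"`.
#' @param speed Speed along the viewing axis, m/s (> 0).
#' @param start_lateral_offset,start_vertical_offset Unsigned offsets of the
#'   start position, metres; signs are taken from `quadrant`.
#' @param impact_lateral_offset Horizontal offset of the would-be impact
#'   point from the nasion, metres (0 = hit nasion; e.g. 0.06 = near miss).
#' @param sphere_diameter Sphere diameter in metres (> 0).
#' @param viewing_distance Eye-to-screen distance in metres (> 0).
#' @param quadrant One of `"UL"`, `"UR"`, `"LL"`, `"LR"`.
#' @param direction `"approach"` (default) or `"recede"`.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(start_distance, end_distance, speed,
                            start_lateral_offset = 0,
                            start_vertical_offset = 0,
                            impact_lateral_offset = 0,
                            sphere_diameter = 0.06,
                            viewing_distance = 1.3,
                            quadrant = c("UR", "UL", "LL", "LR"),
                            direction = c("approach", "recede")) {
  quadrant <- match.arg(quadrant)
  direction <- match.arg(direction)
  if (speed <= 0) stop_domain("`speed` must be > 0")
  if (sphere_diameter <= 0) stop_domain("`sphere_diameter` must be > 0")
  if (viewing_distance <= 0) stop_domain("`viewing_distance` must be > 0")
  if (direction == "approach") {
    if (!(start_distance > end_distance && end_distance >= 0)) {
      stop_domain("approach requires start_distance > end_distance >= 0")
    }
  } else {
    if (!(end_distance > start_distance && start_distance >= 0)) {
      stop_domain("recede requires end_distance > start_distance >= 0")
    }
  }
  structure(
    list(start_distance = start_distance, end_distance = end_distance,
         speed = speed,
         start_lateral_offset = start_lateral_offset,
         start_vertical_offset = start_vertical_offset,
         impact_lateral_offset = impact_lateral_offset,
         sphere_diameter = sphere_diameter,
         viewing_distance = viewing_distance,
         quadrant = quadrant, direction = direction),
    class = "trajectory_spec")
}

quadrant_signs <- function(quadrant) {
  switch(quadrant,
         UL = c(-1, 1), UR = c(1, 1), LL = c(-1, -1), LR = c(1, -1))
}

#' Project a trajectory onto angular (retinal) coordinates
#'
#' Positions are linearly interpolated in 3D between the start point and the
#' would-be impact point; angular coordinates are taken from a cyclopean
#' pinhole eye as `atan(offset / distance)`, and angular size from
#' [angular_diameter()] at each frame's distance.
#'
#' @param spec A [trajectory_spec()].
#' @param n_frames Number of frames (>= 2). Defaults to the 60 Hz frame
#'   count of the travel duration when `NULL`.
#' @param frame_rate Frames per second used when `n_frames` is `NULL`.
#' @return An object of class `projected_path` with fields `frame_times`
#'   (s), `angular_x`, `angular_y`, `angular_size` (deg) and
#'   `centroid_shift` (deg, 0 until aligned).
#' @export
project_trajectory <- function(spec, n_frames = NULL, frame_rate = 60) {
  stopifnot(inherits(spec, "trajectory_spec"))
  duration <- abs(spec$start_distance - spec$end_distance) / spec$speed
  if (is.null(n_frames)) n_frames <- max(2L, floor(duration * frame_rate))
  if (n_frames < 2) stop_domain("`n_frames` must be >= 2")
  sgn <- quadrant_signs(spec$quadrant)

  ## start point and would-be impact point (impact at distance 0)
  p0 <- c(sgn[1] * spec$start_lateral_offset,
          sgn[2] * spec$start_vertical_offset,
          spec$start_distance)
  p_impact <- c(sgn[1] * spec$impact_lateral_offset, 0, 0)

  ## distance runs linearly from start to end; positions lie on the line
  ## start -> impact, parameterised by distance.
  z <- seq(spec$start_distance, spec$end_distance, length.out = n_frames)
  if (any(z[-n_frames] <= 0)) {
    stop_domain("trajectory passes through distance 0 before the final frame")
  }
  frac <- (spec$start_distance - z) / spec$start_distance
  x <- p0[1] + frac * (p_impact[1] - p0[1])
  y <- p0[2] + frac * (p_impact[2] - p0[2])

  zs <- pmax(z, .Machine$double.eps)
  structure(
    list(frame_times = seq(0, duration, length.out = n_frames),
         angular_x = rad2deg(atan(x / zs)),
         angular_y = rad2deg(atan(y / zs)),
         angular_size = angular_diameter(spec$sphere_diameter, zs),
         centroid_shift = c(0, 0),
         quadrant = spec$quadrant),
    class = "projected_path")
}

path_centroid <- function(path) {
  w <- path$angular_size^2   # area-weighted (solid disc)
  c(sum(w * path$angular_x), sum(w * path$angular_y)) / sum(w)
}

#' Align projected paths by their image centre of mass
#'
#' Rigidly shifts each path in angular coordinates so that its time-averaged,
#' area-weighted image centroid coincides with the across-path mean centroid.
#' This is the retinotopic alignment applied to trajectory conditions from
#' the same quadrant so that conditions differ only in motion, not in mean
#' retinal position.
#'
#' @param paths A list of `projected_path` objects (>= 2, same quadrant).
#' @return The list of paths, shifted; each carries its applied shift in
#'   `centroid_shift`.
#' @export
align_by_centroid <- function(paths) {
  if (length(paths) == 0) stop_domain("`paths` must not be empty")
  stopifnot(all(vapply(paths, inherits, logical(1), "projected_path")))
  if (length(paths) < 2) stop_domain("need at least 2 paths to align")
  quad <- vapply(paths, function(p) p$quadrant %||% NA_character_, character(1))
  if (length(unique(quad[!is.na(quad)])) > 1) {
    stop_domain("all paths must come from the same quadrant")
  }
  cents <- vapply(paths, path_centroid, numeric(2))
  target <- rowMeans(cents)
  out <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    shift <- target - cents[, i]
    p$angular_x <- p$angular_x + shift[1]
    p$angular_y <- p$angular_y + shift[2]
    p$centroid_shift <- p$centroid_shift + shift
    p
  })
  names(out) <- names(paths)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a projected path into a luminance frame stack
#'
#' Draws an anti-aliased disc of the per-frame angular size at the per-frame
#' angular position on a constant background. Fixation is at the raster
#' centre; pixel values are luminance fractions in \[0, 1\].
#'
#' @param path A `projected_path`.
#' @param resolution Raster side length in pixels (>= 32).
#' @param field_of_view Full width of the raster in degrees.
#' @param texture `"solid"` or `"checkerboard"`.
#' @param polarity `"bright_on_dark"` or `"dark_on_bright"`.
#' @param background_level Background luminance fraction.
#' @param frame_rate Frames per second recorded in the output.
#' @param check_size_deg Check size for the checkerboard texture, degrees.
#' @return An object of class `frame_sequence`: `frames` (array
#'   `resolution x resolution x n`), `pixel_pitch` (deg/px), `frame_rate`,
#'   `background_level`.
#' @export
render_frames <- function(path, resolution = 256, field_of_view = 12,
                          texture = c("solid", "checkerboard"),
                          polarity = c("bright_on_dark", "dark_on_bright"),
                          background_level = NULL, frame_rate = 60,
                          check_size_deg = 0.25) {
  texture <- match.arg(texture)
  polarity <- match.arg(polarity)
  stopifnot(inherits(path, "projected_path"))
  if (resolution < 32) stop_domain("`resolution` must be >= 32")
  pitch <- field_of_view / resolution
  if (is.null(background_level)) {
    background_level <- if (polarity == "bright_on_dark") 0.25 else 0.75
  }
  disc_level <- if (polarity == "bright_on_dark") 1 else 0

  ax <- (seq_len(resolution) - (resolution + 1) / 2) * pitch
  ay <- rev(ax)  # +y upward: first row is the top of the field
  n <- length(path$frame_times)
  frames <- array(background_level, dim = c(resolution, resolution, n))
  half_fov <- field_of_view / 2
  clipped <- FALSE

  for (k in seq_len(n)) {
    r <- path$angular_size[k] / 2
    if (r <= 0) next
    cx <- path$angular_x[k]
    cy <- path$angular_y[k]
    if (abs(cx) + r > half_fov || abs(cy) + r > half_fov) clipped <- TRUE
    dx <- ax - cx
    dy <- ay - cy
    d <- sqrt(outer(dy^2, dx^2, `+`))
    ## per-pixel coverage: linear anti-aliasing ramp one pixel wide
    cov <- pmin(pmax((r - d) / pitch + 0.5, 0), 1)
    lvl <- disc_level
    if (texture == "checkerboard") {
      chk <- outer(floor(ay / check_size_deg), floor(ax / check_size_deg), `+`)
      lvl <- ifelse(chk %% 2 == 0, disc_level, 1 - disc_level)
      frames[, , k] <- background_level * (1 - cov) + lvl * cov
    } else {
      frames[, , k] <- background_level * (1 - cov) + lvl * cov
    }
  }
  if (clipped) warning("disc exceeds the field of view; clipped at raster edge")
  structure(list(frames = frames, pixel_pitch = pitch,
                 frame_rate = frame_rate,
                 background_level = background_level),
            class = "frame_sequence")
}

#' Balanced randomized trial schedule
#'
#' Builds a per-run trial table with balanced factor cells, a seeded random
#' order, and inter-stimulus intervals drawn uniformly from a configured set.
#'
#' @param factors Named list of factor levels, e.g.
#'   `list(trajectory = c("hit", "miss"), quadrant = c("UL","UR","LL","LR"))`.
#' @param runs Number of runs.
#' @param trials_per_run Trials per run; must be divisible by the number of
#'   factor cells.
#' @param isi_choices Possible inter-stimulus intervals in seconds.
#' @param seed Integer seed; same seed gives a bit-identical schedule.
#' @param stimulus_duration Stimulus duration in seconds (enters onsets).
#' @return A `data.frame` with columns `run`, `trial_index`, one column per
#'   factor, `onset_time` and `isi`; the factor definition and seed are
#'   attached as attributes.
#' @export
make_trial_schedule <- function(factors, runs, trials_per_run, isi_choices,
                                seed, stimulus_duration = 0.33) {
  stopifnot(is.list(factors), length(factors) >= 1, runs >= 1)
  cells <- expand.grid(factors, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  n_cells <- nrow(cells)
  if (trials_per_run %% n_cells != 0) {
    stop_domain("`trials_per_run` (", trials_per_run,
                ") is not divisible by the number of factor cells (",
                n_cells, ")")
  }
  reps <- trials_per_run / n_cells
  with_seed(seed, {
    out <- lapply(seq_len(runs), function(r) {
      idx <- sample(rep(seq_len(n_cells), reps))
      isi <- sample(isi_choices, trials_per_run, replace = TRUE)
      onset <- cumsum(c(isi[1],
                        rep(stimulus_duration, trials_per_run - 1) +
                          isi[-1]))
      cbind(data.frame(run = r, trial_index = seq_len(trials_per_run)),
            cells[idx, , drop = FALSE],
            data.frame(onset_time = onset, isi = isi))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    attr(out, "factors") <- factors
    attr(out, "seed") <- seed
    out
  })
}

#' Vertical and horizontal components of an eccentric stimulus position
#'
#' Decomposes an eccentricity given as (eccentricity, polar angle from the
#' vertical meridian) into signed horizontal and vertical screen offsets in
#' degrees.
#'
#' @param eccentricity_deg Eccentricity in degrees.
#' @param polar_angle_deg Angle from the vertical meridian in degrees.
#' @return Named vector `c(horizontal, vertical)` in degrees.
#' @export
eccentricity_components <- function(eccentricity_deg, polar_angle_deg) {
  c(horizontal = eccentricity_deg * sin(deg2rad(polar_angle_deg)),
    vertical = eccentricity_deg * cos(deg2rad(polar_angle_deg)))
}
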