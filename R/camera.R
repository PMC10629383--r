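#' Camera model
#'
#' Pinhole camera with a rigid mount tilt about the along-track (forward)
#' axis. Positive `mount_tilt` swings the optical axis toward the
#' starboard (+across-track) side; the paired camera uses the opposite
#' sign so the two swaths meet under the aircraft with a small side-lap.
#'
#' @param focal_length Focal length (m).
#' @param sensor_width Sensor extent across-track (m).
#' @param sensor_height Sensor extent along-track (m).
#' @param pixels Length-2 integer `(cols, rows)`.
#' @param mount_tilt Signed tilt from vertical about the along-track axis
#'   (degrees), `|tilt| < 90`.
#' @return An object of class `camera_model`.
#' @examples
#' north_cam <- camera_model(mount_tilt = 11.5)
#' @export
camera_model <- function(focal_length = 0.050,
                         sensor_width = 0.0232,
                         sensor_height = 0.0154,
                         pixels = c(6016L, 4000L),
                         mount_tilt = 11.5) {
  if (focal_length <= 0) stop("camera_model: focal_length must be > 0")
  if (abs(mount_tilt) >= 90) stop("camera_model: |mount_tilt| must be < 90")
  structure(list(focal_length = focal_length,
                 sensor_width = sensor_width,
                 sensor_height = sensor_height,
                 pixels = as.integer(pixels),
                 mount_tilt = mount_tilt),
            class = "camera_model")
}

#' Camera pose
#'
#' Position and attitude of the airframe at a capture instant, in a local
#' planar metric frame (easting/northing in metres, altitude above the sea
#' surface). Azimuth is the heading in degrees clockwise from north;
#' pitch rotates about the across-track axis (positive shifts the view
#' forward) and roll about the along-track axis (positive shifts the view
#' to starboard).
#'
#' @param easting,northing,altitude Position (m); `altitude > 0`.
#' @param pitch,roll,azimuth Attitude (degrees).
#' @param time Capture time (s).
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(easting = 0, northing = 0, altitude = 396,
                        pitch = 0, roll = 0, azimuth = 0, time = 0) {
  if (altitude <= 0) stop("camera_pose: altitude must be > 0")
  structure(list(easting = easting, northing = northing, altitude = altitude,
                 pitch = pitch, roll = roll, azimuth = azimuth, time = time),
            class = "camera_pose")
}

rot_about_forward <- function(deg) {   # tilt / roll, about body y (forward)
  t <- deg * pi / 180
  matrix(c(cos(t), 0, -sin(t),
           0, 1, 0,
           sin(t), 0, cos(t)), 3L, 3L, byrow = TRUE)
}

rot_about_across <- function(deg) {    # pitch, about body x (starboard)
  t <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(t), -sin(t),
           0, sin(t), cos(t)), 3L, 3L, byrow = TRUE)
}

rot_azimuth <- function(deg) {         # heading, clockwise from north
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3L, 3L, byrow = TRUE)
}

# World direction of the rays through sensor points (xs, ys) metres from the
# principal point. Composition order: mount tilt (camera->body), then roll,
# then pitch (body attitude), then azimuth (body->world).
ray_directions <- function(pose, camera, xs, ys) {
  d0 <- rbind(xs, ys, rep(-camera$focal_length, length(xs)))
  R <- rot_azimuth(pose$azimuth) %*% rot_about_across(pose$pitch) %*%
    rot_about_forward(pose$roll) %*% rot_about_forward(camera$mount_tilt)
  R %*% d0
}

#' Project a pixel onto the sea surface
#'
#' Intersects the pinhole ray through a pixel -- rotated by the camera
#' mount tilt, the airframe roll, pitch and azimuth -- with the plane
#' z = 0. Pixel coordinates run from `(0, 0)` at the top-left sensor
#' corner to `(cols, rows)`; the principal point is `(cols/2, rows/2)`.
#'
#' @param pose A `camera_pose`.
#' @param camera A `camera_model`.
#' @param pixel Length-2 numeric `(col, row)` or an n x 2 matrix.
#' @return Numeric `(easting, northing)` or an n x 2 matrix.
#' @examples
#' # nadir identity
#' project_pixel_to_ground(camera_pose(0, 0, 396),
#'                         camera_model(mount_tilt = 0), c(3008, 2000))
#' @export
project_pixel_to_ground <- function(pose, camera, pixel) {
  if (pose$altitude <= 0) stop("project_pixel_to_ground: altitude must be > 0")
  px <- matrix(as.numeric(pixel), ncol = 2L)
  xs <- (px[, 1L] / camera$pixels[1L] - 0.5) * camera$sensor_width
  ys <- (0.5 - px[, 2L] / camera$pixels[2L]) * camera$sensor_height
  d <- ray_directions(pose, camera, xs, ys)
  dz <- d[3L, ]
  if (any(dz >= -1e-12))
    stop("project_pixel_to_ground: ray at or above the horizon")
  s <- pose$altitude / (-dz)
  out <- cbind(easting = pose$easting + s * d[1L, ],
               northing = pose$northing + s * d[2L, ])
  if (nrow(out) == 1L) drop(out) else out
}

#' Ground footprint of one camera frame
#'
#' Projects the four sensor corners onto the sea surface and assembles the
#' counter-clockwise footprint quadrilateral, plus the centre-pixel ground
#' sample distance (across-track spacing of adjacent pixel centres on the
#' ground).
#'
#' @inheritParams project_pixel_to_ground
#' @param image_id,camera_id Optional identifiers carried through.
#' @return An object of class `image_footprint`: list with `corners`
#'   (4 x 2, CCW), `polygon` (alias of corners), `gsd_centre` (m/px),
#'   `image_id`, `camera_id`, `capture_time`.
#' @export
image_footprint <- function(pose, camera, image_id = NA, camera_id = NA) {
  cols <- camera$pixels[1L]; rows <- camera$pixels[2L]
  corners_px <- rbind(c(0, 0), c(cols, 0), c(cols, rows), c(0, rows))
  corners <- project_pixel_to_ground(pose, camera, corners_px)
  corners <- ensure_ccw(corners)
  centre <- project_pixel_to_ground(pose, camera, c(cols / 2, rows / 2))
  nb <- project_pixel_to_ground(pose, camera, c(cols / 2 + 1, rows / 2))
  structure(list(image_id = image_id, camera_id = camera_id,
                 corners = corners, polygon = corners,
                 gsd_centre = sqrt(sum((nb - centre)^2)),
                 capture_time = pose$time),
            class = "image_footprint")
}

fp_poly <- function(x) if (inherits(x, "image_footprint")) x$polygon else x

#' Forward-lap between two frames of one camera
#'
#' Fraction of the first footprint's area covered by the second,
#' `area(a intersect b) / area(a)`.
#'
#' @param fp_a,fp_b Footprints (`image_footprint` or polygon matrices) of
#'   consecutive captures from the same camera.
#' @return Fraction in `[0, 1]`; 0 for disjoint footprints.
#' @export
forward_overlap <- function(fp_a, fp_b) {
  a <- fp_poly(fp_a); b <- fp_poly(fp_b)
  inter <- convex_clip(a, b)
  if (nrow(inter) < 3L) return(0)
  min(1, poly_area(inter) / poly_area(a))
}

#' Side-lap between the two camera coverages
#'
#' Ratio of the area of intersection of the two dissolved per-camera
#' coverages to the per-camera coverage area (the mean of the two, which
#' are equal by design).
#'
#' @param union_cam1,union_cam2 Dissolved coverage of each camera: a
#'   polygon matrix or a list of footprint polygons.
#' @return Fraction in `[0, 1]`.
#' @export
side_overlap <- function(union_cam1, union_cam2) {
  a1 <- dissolve_coverage(union_cam1)$area
  a2 <- dissolve_coverage(union_cam2)$area
  if (a1 <= 0 || a2 <= 0) stop("side_overlap: empty coverage polygon")
  inter <- coverage_intersection_area(union_cam1, union_cam2)
  inter / mean(c(a1, a2))
}

#' Dissolve footprints into total covered area
#'
#' Area of the union of all footprints: ground covered by at least one
#' image is counted once regardless of forward- or side-lap.
#'
#' @param footprints A polygon matrix, an `image_footprint`, or a list of
#'   either.
#' @return List with `area` (m^2) and `polygons` (the input polygons).
#' @export
dissolve_coverage <- function(footprints) {
  if (inherits(footprints, "image_footprint") || is.matrix(footprints))
    footprints <- list(footprints)
  if (length(footprints) == 0L) stop("dissolve_coverage: no footprints")
  polys <- lapply(footprints, fp_poly)
  list(area = union_area(polys), polygons = polys)
}

#' Cut a coverage into transect segments
#'
#' Clips a coverage (list of convex footprints) into slabs perpendicular
#' to the transect direction and returns the covered (dissolved) area per
#' segment. Chainage of a point is its projection onto the transect
#' direction measured from `origin`.
#'
#' @param coverage Polygon matrix or list of convex polygons.
#' @param boundaries Increasing numeric vector of segment boundary
#'   chainages (length `n_segments + 1`).
#' @param origin Length-2 point on the transect (chainage 0).
#' @param heading Transect heading, degrees clockwise from north.
#' @return Numeric vector of per-segment covered areas (m^2).
#' @export
cut_by_segments <- function(coverage, boundaries, origin = c(0, 0),
                            heading = 0) {
  if (is.matrix(coverage) || inherits(coverage, "image_footprint"))
    coverage <- list(coverage)
  polys <- lapply(coverage, fp_poly)
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("cut_by_segments: boundaries must be strictly increasing")
  a <- deg2rad(heading)
  u <- c(sin(a), cos(a))                      # unit vector along transect
  b0 <- sum(u * origin)
  nseg <- length(boundaries) - 1L
  areas <- numeric(nseg)
  ch <- lapply(polys, function(p) range(p %*% u - b0))
  for (k in seq_len(nseg)) {
    lo <- boundaries[k]; hi <- boundaries[k + 1L]
    pieces <- list()
    for (i in seq_along(polys)) {
      if (ch[[i]][2L] <= lo || ch[[i]][1L] >= hi) next
      p <- clip_halfplane(polys[[i]], -u, -(lo + b0))   # chainage >= lo
      p <- clip_halfplane(p, u, hi + b0)                # chainage <= hi
      if (nrow(p) >= 3L) pieces <- c(pieces, list(p))
    }
    areas[k] <- union_area(pieces)
  }
  areas
}

deg2rad <- function(deg) deg * pi / 180

#' Capture interval for a prescribed forward-lap
#'
#' The along-track footprint length at nominal altitude is
#' `altitude * sensor_height / focal_length`; capturing every
#' `length * (1 - lap) / speed` seconds yields the prescribed forward-lap.
#'
#' @param config A `survey_config`.
#' @return Interval between captures (s).
#' @examples
#' cfg <- survey_config(drone_altitude = 427)
#' schedule_capture_interval(cfg)  # ~2.56 s
#' @export
schedule_capture_interval <- function(config) {
  if (config$target_forward_lap >= 1)
    stop("schedule_capture_interval: forward-lap must be < 1")
  len <- config$drone_altitude * config$sensor_height /
    config$camera_focal_length
  len * (1 - config$target_forward_lap) / config$ground_speed
}

#' Effective area sampled by the observer team
#'
#' Observer strips scale with altitude, so the sampled area of a segment is
#' the altitude fraction (mean altitude over target altitude) times segment
#' length times the combined nominal strip width.
#'
#' @param segment_length Segment length (m), > 0.
#' @param mean_altitude Mean recorded altitude over the segment (m).
#' @param config A `survey_config`.
#' @return Area (m^2).
#' @examples
#' observer_effective_area(1000, 152, survey_config())  # 409000
#' @export
observer_effective_area <- function(segment_length, mean_altitude, config) {
  if (any(segment_length <= 0))
    stop("observer_effective_area: segment_length must be > 0")
  if (any(mean_altitude <= 0))
    stop("observer_effective_area: mean_altitude must be > 0")
  (mean_altitude / config$observer_target_altitude) * segment_length *
    sum(config$observer_strip_widths)
}

#' Map observer calls to ground points
#'
#' Places each call at the centre of its 50 m zone, abeam of the aircraft
#' position interpolated at the time the group was called abeam. The
#' lateral offset is `(gap/2 + 50 * zone + 25)` scaled by the altitude
#' fraction, to port (left of heading) or starboard.
#'
#' @param calls Data frame with columns `time`, `side` ("port"/"starboard")
#'   and `zone` (0-based 50 m bin from the strip inner edge).
#' @param track Data frame with columns `time`, `easting`, `northing` and
#'   optionally `altitude`, ordered by time.
#' @param config A `survey_config`.
#' @return `calls` with added `easting` and `northing` columns.
#' @export
map_observer_sighting <- function(calls, track, config) {
  if (any(calls$time < min(track$time) | calls$time > max(track$time)))
    stop("map_observer_sighting: call time outside track time span")
  ex <- stats::approx(track$time, track$easting, xout = calls$time)$y
  ny <- stats::approx(track$time, track$northing, xout = calls$time)$y
  alt <- if ("altitude" %in% names(track))
    stats::approx(track$time, track$altitude, xout = calls$time)$y
  else rep(config$observer_target_altitude, nrow(calls))
  # heading from local track direction
  n <- nrow(track)
  i <- pmin(pmax(findInterval(calls$time, track$time), 1L), n - 1L)
  dx <- track$easting[i + 1L] - track$easting[i]
  dy <- track$northing[i + 1L] - track$northing[i]
  hlen <- sqrt(dx^2 + dy^2)
  hlen[hlen == 0] <- 1
  ux <- dx / hlen; uy <- dy / hlen           # along-track unit vector
  rx <- uy; ry <- -ux                        # starboard unit vector
  frac <- alt / config$observer_target_altitude
  lateral <- (config$observer_gap / 2 + 50 * calls$zone + 25) * frac
  sgn <- ifelse(calls$side == "starboard", 1, -1)
  calls$easting <- ex + sgn * lateral * rx
  calls$northing <- ny + sgn * lateral * ry
  calls
}
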