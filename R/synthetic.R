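#' @name synthetic-surveys
#' @title Synthetic dual-platform surveys with known ground truth
#'
#' @description
#' Forward model for a paired observer/drone strip-transect survey in a
#' local planar metric frame. Transects run due north; the observer
#' aircraft carries a front- and back-seat observer on each side watching
#' two lateral strips separated by a central gap, while the drone's two
#' tilted cameras image a continuous swath under the flight line. Animal
#' groups are a Poisson process with stratum-specific intensity,
#' heavy-tailed zero-truncated group sizes, and members scattered within a
#' cluster radius chosen so a 200 m chain rule keeps generated groups
#' intact. Detection is a per-occasion Bernoulli thinning of available,
#' covered groups: when an occasion (observer seat or image reviewer)
#' detects a group it records all covered members, which mirrors how
#' observers call whole groups and reviewers mark every visible animal.
NULL

#' Zero-truncated count samplers
#'
#' Inverse-CDF samplers for the Poisson and negative binomial families
#' conditioned on being at least 1. The zero-truncated Poisson with rate
#' `lambda` has mean `lambda / (1 - exp(-lambda))`.
#'
#' @param n Number of draws.
#' @param lambda Poisson rate (untruncated).
#' @param size,mu Negative binomial size (dispersion) and mean
#'   (untruncated).
#' @return Integer vector of draws, all >= 1.
#' @export
rztpois <- function(n, lambda) {
  p0 <- stats::ppois(0, lambda)
  u <- stats::runif(n, p0, 1)
  pmax(1L, stats::qpois(u, lambda))
}

#' @rdname rztpois
#' @export
rztnbinom <- function(n, size, mu) {
  p0 <- stats::pnbinom(0, size = size, mu = mu)
  u <- stats::runif(n, p0, 1)
  pmax(1L, stats::qnbinom(u, size = size, mu = mu))
}

#' Lay out parallel transect centrelines
#'
#' Transects run due north, spaced `transect_spacing` apart along the
#' easting axis, all starting at northing 0. Deterministic for a fixed
#' config.
#'
#' @param config A [survey_config()].
#' @return Data frame with `transect_id`, `easting`, `northing_start`,
#'   `northing_end`, `length`, `heading`.
#' @export
generate_transect_layout <- function(config) {
  stopifnot(config$n_transects >= 1L)
  data.frame(
    transect_id = seq_len(config$n_transects),
    easting = (seq_len(config$n_transects) - 1L) * config$transect_spacing,
    northing_start = 0,
    northing_end = config$transect_length,
    length = config$transect_length,
    heading = 0
  )
}

#' Generate clustered animal groups
#'
#' Group centroids are a homogeneous Poisson process within a band of
#' `band_halfwidth` either side of each transect centreline, with
#' per-transect intensity `density_by_stratum` (groups per km^2). Sizes
#' come from `group_size_law`; each member is placed uniformly in a disc
#' of radius `cluster_radius` around the centroid, so members of one group
#' are never more than `2 * cluster_radius` apart.
#'
#' @param config A [survey_config()].
#' @param density_by_stratum Groups per km^2; scalar or one value per
#'   transect.
#' @param group_size_law Function `n -> integer sizes >= 1`. Default:
#'   zero-truncated negative binomial with size 0.8 and (untruncated)
#'   mean 1.6.
#' @param seed Integer seed.
#' @param band_halfwidth Half-width of the populated band (m).
#' @param cluster_radius Member scatter radius (m); keep `<= 100` so a
#'   200 m chain rule cannot split a group.
#' @param availability Length-2 numeric `(observer, imagery)` probability
#'   that a group is at the surface during each platform's pass.
#' @return List of class `survey_truth` with data frames `groups`
#'   (`group_id`, `transect_id`, `centroid_e`, `centroid_n`, `size`,
#'   `available_observer`, `available_imagery`) and `members`
#'   (`group_id`, `member_id`, `easting`, `northing`).
#' @export
generate_groups <- function(config,
                            density_by_stratum = 0.5,
                            group_size_law = function(n) rztnbinom(n, 0.8, 1.6),
                            seed = config$seed,
                            band_halfwidth = 500,
                            cluster_radius = 100,
                            availability = c(observer = 1, imagery = 1)) {
  if (any(density_by_stratum < 0))
    stop("generate_groups: densities must be >= 0")
  if (any(availability < 0 | availability > 1))
    stop("generate_groups: availability must be in [0, 1]")
  set.seed(seed)
  layout <- generate_transect_layout(config)
  dens <- rep_len(density_by_stratum, nrow(layout))
  area_km2 <- (2 * band_halfwidth / 1000) * (config$transect_length / 1000)
  groups <- list(); members <- list(); gid <- 0L
  for (k in seq_len(nrow(layout))) {
    n_k <- stats::rpois(1L, dens[k] * area_km2)
    if (n_k == 0L) next
    cx <- stats::runif(n_k, layout$easting[k] - band_halfwidth,
                       layout$easting[k] + band_halfwidth)
    cy <- stats::runif(n_k, layout$northing_start[k], layout$northing_end[k])
    sizes <- as.integer(group_size_law(n_k))
    stopifnot(all(sizes >= 1L))
    ids <- gid + seq_len(n_k); gid <- gid + n_k
    groups[[length(groups) + 1L]] <- data.frame(
      group_id = ids, transect_id = layout$transect_id[k],
      centroid_e = cx, centroid_n = cy, size = sizes,
      available_observer = stats::rbinom(n_k, 1L, availability[1L]) == 1L,
      available_imagery = stats::rbinom(n_k, 1L, availability[2L]) == 1L)
    m <- sum(sizes)
    r <- cluster_radius * sqrt(stats::runif(m))
    th <- stats::runif(m, 0, 2 * pi)
    members[[length(members) + 1L]] <- data.frame(
      group_id = rep(ids, sizes),
      member_id = sequence(sizes),
      easting = rep(cx, sizes) + r * cos(th),
      northing = rep(cy, sizes) + r * sin(th))
  }
  empty_g <- data.frame(group_id = integer(), transect_id = integer(),
                        centroid_e = numeric(), centroid_n = numeric(),
                        size = integer(), available_observer = logical(),
                        available_imagery = logical())
  empty_m <- data.frame(group_id = integer(), member_id = integer(),
                        easting = numeric(), northing = numeric())
  structure(list(
    groups = if (length(groups)) do.call(rbind, groups) else empty_g,
    members = if (length(members)) do.call(rbind, members) else empty_m),
    class = "survey_truth")
}

# start time of each transect pass for a platform flying at `speed`,
# with a fixed turn-around time between transects
transect_start_times <- function(config, speed, turn_time = 600) {
  (seq_len(config$n_transects) - 1L) *
    (config$transect_length / speed + turn_time)
}

#' Generate drone telemetry
#'
#' One pose per capture instant per transect, both cameras firing
#' simultaneously. Capture times follow [schedule_capture_interval()];
#' attitude noise is Gaussian and altitude wanders around nominal.
#'
#' @param config A [survey_config()].
#' @param seed Integer seed.
#' @param sigma_pitch,sigma_roll,sigma_azimuth Attitude noise SD (deg).
#'   Azimuth noise models the crab angle.
#' @param sigma_alt Altitude noise SD (m).
#' @return Data frame `images`: `image_id`, `camera_id` ("cam1" tilted to
#'   starboard/east, "cam2" to port/west), `transect_id`, `time`,
#'   `easting`, `northing`, `altitude`, `pitch`, `roll`, `azimuth`.
#' @export
generate_telemetry <- function(config, seed = config$seed,
                               sigma_pitch = 2, sigma_roll = 2,
                               sigma_azimuth = 1, sigma_alt = 3) {
  stopifnot(config$ground_speed > 0)
  set.seed(seed)
  layout <- generate_transect_layout(config)
  dt <- schedule_capture_interval(config)
  t0 <- transect_start_times(config, config$ground_speed)
  rows <- list()
  for (k in seq_len(nrow(layout))) {
    tt <- seq(0, config$transect_length / config$ground_speed, by = dt)
    n <- length(tt)
    pose <- data.frame(
      transect_id = layout$transect_id[k],
      time = t0[k] + tt,
      easting = layout$easting[k],
      northing = layout$northing_start[k] + tt * config$ground_speed,
      altitude = config$drone_altitude + stats::rnorm(n, 0, sigma_alt),
      pitch = stats::rnorm(n, 0, sigma_pitch),
      roll = stats::rnorm(n, 0, sigma_roll),
      azimuth = layout$heading[k] + stats::rnorm(n, 0, sigma_azimuth))
    rows[[k]] <- rbind(
      cbind(camera_id = "cam1", pose),
      cbind(camera_id = "cam2", pose))
  }
  images <- do.call(rbind, rows)
  images <- images[order(images$time, images$camera_id), ]
  images$image_id <- sprintf("im%06d", seq_len(nrow(images)))
  rownames(images) <- NULL
  images[, c("image_id", "camera_id", "transect_id", "time", "easting",
             "northing", "altitude", "pitch", "roll", "azimuth")]
}

#' Cameras of the survey payload
#'
#' @param config A [survey_config()].
#' @return Named list of two [camera_model()]s: `cam1` tilted `+mount_tilt`
#'   (starboard), `cam2` tilted `-mount_tilt` (port).
#' @export
survey_cameras <- function(config) {
  mk <- function(s) camera_model(config$camera_focal_length,
                                 config$sensor_width, config$sensor_height,
                                 config$sensor_pixels, s * config$mount_tilt)
  list(cam1 = mk(1), cam2 = mk(-1))
}

#' Footprints for a telemetry table
#'
#' @param images Telemetry data frame from [generate_telemetry()] (or the
#'   same schema read from `images.csv`).
#' @param config A [survey_config()].
#' @return Named list of `image_footprint` objects keyed by `image_id`.
#' @export
footprints_from_images <- function(images, config) {
  cams <- survey_cameras(config)
  fps <- vector("list", nrow(images))
  for (i in seq_len(nrow(images))) {
    r <- images[i, ]
    pose <- camera_pose(r$easting, r$northing, r$altitude,
                        r$pitch, r$roll, r$azimuth, r$time)
    fps[[i]] <- image_footprint(pose, cams[[r$camera_id]],
                                image_id = r$image_id,
                                camera_id = r$camera_id)
  }
  names(fps) <- images$image_id
  fps
}

# lateral strip bounds (easting offsets from centreline) for each observer
# side at nominal altitude
observer_strip_bounds <- function(config) {
  half_gap <- config$observer_gap / 2
  list(port = c(-(half_gap + config$observer_strip_widths["port"]), -half_gap),
       starboard = c(half_gap, half_gap + config$observer_strip_widths["starboard"]))
}

#' Generate detections for one platform
#'
#' Each available group whose members fall inside the platform's covered
#' region is detected independently by occasion `i` (observer seat or image
#' reviewer) with probability `p[i]`; a detecting occasion records all
#' covered members. Observer calls carry side, 50 m zone and time abeam;
#' imagery detections carry pixel coordinates in every frame whose
#' footprint contains the animal.
#'
#' @param truth A `survey_truth` from [generate_groups()].
#' @param platform_spec List with `platform` ("observer" or "imagery") and
#'   `p` (per-occasion detection probabilities: `c(front, back)` for
#'   observers, one per reviewer for imagery), plus optional
#'   `uncertain_rate` (imagery; fraction of detections flagged uncertain)
#'   and `calf_rate`.
#' @param config A [survey_config()].
#' @param seed Integer seed.
#' @param footprints Imagery only: list from [footprints_from_images()].
#' @param images Imagery only: telemetry data frame (for per-image lookup).
#' @return For observers, a data frame of calls (`call_id`, `transect_id`,
#'   `seat`, `side`, `zone`, `time`, `size`, `true_group_id`). For
#'   imagery, a data frame of detections (`detection_id`, `reviewer_id`,
#'   `image_id`, `easting`, `northing`, `pixel_col`, `pixel_row`,
#'   `certainty`, `calf`, `true_group_id`, `true_member_id`).
#' @export
generate_detections <- function(truth, platform_spec, config,
                                seed = config$seed,
                                footprints = NULL, images = NULL) {
  p <- platform_spec$p
  if (any(p < 0 | p > 1))
    stop("generate_detections: probabilities must be in [0, 1]")
  set.seed(seed)
  if (identical(platform_spec$platform, "observer"))
    observer_detections(truth, p, config)
  else if (identical(platform_spec$platform, "imagery"))
    imagery_detections(truth, p, config, footprints, images,
                       uncertain_rate = platform_spec$uncertain_rate %||% 0,
                       calf_rate = platform_spec$calf_rate %||% 0)
  else stop("generate_detections: unknown platform")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

observer_detections <- function(truth, p, config) {
  layout <- generate_transect_layout(config)
  bounds <- observer_strip_bounds(config)
  t0 <- transect_start_times(config, config$observer_speed)
  g <- truth$groups
  out <- list()
  if (nrow(g)) for (i in seq_len(nrow(g))) {
    if (!g$available_observer[i]) next
    tx <- layout$easting[match(g$transect_id[i], layout$transect_id)]
    mem <- truth$members[truth$members$group_id == g$group_id[i], ]
    off <- mem$easting - tx
    side <- if (g$centroid_e[i] < tx) "port" else "starboard"
    b <- bounds[[side]]
    covered <- off >= b[1L] & off <= b[2L]
    if (!any(covered)) next
    n_cov <- sum(covered)
    lat <- abs(mean(off[covered]))
    zone <- max(0L, min(3L, floor((lat - config$observer_gap / 2) / 50)))
    tm <- t0[match(g$transect_id[i], layout$transect_id)] +
      (mean(mem$northing[covered]) -
         layout$northing_start[match(g$transect_id[i], layout$transect_id)]) /
      config$observer_speed
    for (seat_i in seq_along(p)) {
      if (stats::runif(1) <= p[seat_i]) {
        out[[length(out) + 1L]] <- data.frame(
          transect_id = g$transect_id[i],
          seat = c("front", "back")[seat_i], side = side, zone = zone,
          time = tm, size = n_cov, true_group_id = g$group_id[i])
      }
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(transect_id = integer(), seat = character(),
               side = character(), zone = integer(), time = numeric(),
               size = integer(), true_group_id = integer())
  if (nrow(calls)) {
    calls <- calls[order(calls$time, calls$seat), ]
    calls$call_id <- seq_len(nrow(calls))
    rownames(calls) <- NULL
  } else calls$call_id <- integer()
  calls
}

imagery_detections <- function(truth, p, config, footprints, images,
                               uncertain_rate = 0, calf_rate = 0) {
  if (is.null(footprints) || is.null(images))
    stop("imagery detections need footprints and images")
  cams <- survey_cameras(config)
  mem <- truth$members
  g <- truth$groups
  out <- list()
  if (nrow(mem)) {
    # which frames contain each member (bbox prefilter, exact polygon test)
    fp_bb <- t(vapply(footprints, function(f) poly_bbox(f$polygon),
                      numeric(4L)))
    for (i in seq_len(nrow(g))) {
      if (!g$available_imagery[i]) next
      mm <- mem[mem$group_id == g$group_id[i], ]
      hits <- list()
      for (j in seq_len(nrow(mm))) {
        pt <- c(mm$easting[j], mm$northing[j])
        cand <- which(fp_bb[, 1L] <= pt[1L] & fp_bb[, 3L] >= pt[1L] &
                        fp_bb[, 2L] <= pt[2L] & fp_bb[, 4L] >= pt[2L])
        inside <- cand[vapply(cand, function(k)
          points_in_convex(matrix(pt, 1L), footprints[[k]]$polygon), TRUE)]
        if (length(inside))
          hits[[length(hits) + 1L]] <- data.frame(member_row = j,
                                                  fp_idx = inside)
      }
      if (!length(hits)) next                       # group outside coverage
      hits <- do.call(rbind, hits)
      certain_member <- stats::runif(nrow(mm)) >= uncertain_rate
      calf_member <- stats::runif(nrow(mm)) < calf_rate
      for (r in seq_along(p)) {
        if (stats::runif(1) > p[r]) next            # reviewer missed group
        for (h in seq_len(nrow(hits))) {
          j <- hits$member_row[h]; k <- hits$fp_idx[h]
          fp <- footprints[[k]]
          im <- images[match(fp$image_id, images$image_id), ]
          px <- ground_to_pixel(c(mm$easting[j], mm$northing[j]),
                                im, cams[[fp$camera_id]])
          out[[length(out) + 1L]] <- data.frame(
            reviewer_id = r, image_id = fp$image_id,
            transect_id = im$transect_id,
            easting = mm$easting[j], northing = mm$northing[j],
            pixel_col = px[1L], pixel_row = px[2L],
            certainty = if (certain_member[j]) "certain" else "uncertain",
            calf = calf_member[j],
            true_group_id = g$group_id[i], true_member_id = mm$member_id[j])
        }
      }
    }
  }
  det <- if (length(out)) do.call(rbind, out) else
    data.frame(reviewer_id = integer(), image_id = character(),
               transect_id = integer(), easting = numeric(),
               northing = numeric(), pixel_col = numeric(),
               pixel_row = numeric(), certainty = character(),
               calf = logical(), true_group_id = integer(),
               true_member_id = integer())
  det$detection_id <- seq_len(nrow(det))
  rownames(det) <- NULL
  det
}

# invert the pinhole projection for a known ground point
ground_to_pixel <- function(pt, image_row, camera) {
  pose <- camera_pose(image_row$easting, image_row$northing,
                      image_row$altitude, image_row$pitch,
                      image_row$roll, image_row$azimuth, image_row$time)
  d_world <- c(pt[1L] - pose$easting, pt[2L] - pose$northing, -pose$altitude)
  R <- rot_azimuth(pose$azimuth) %*% rot_about_across(pose$pitch) %*%
    rot_about_forward(pose$roll) %*% rot_about_forward(camera$mount_tilt)
  d_cam <- t(R) %*% d_world
  xs <- -camera$focal_length * d_cam[1L] / d_cam[3L]
  ys <- -camera$focal_length * d_cam[2L] / d_cam[3L]
  c(col = (xs / camera$sensor_width + 0.5) * camera$pixels[1L],
    row = (0.5 - ys / camera$sensor_height) * camera$pixels[2L])
}

# piecewise-constant runs of categorical scores along a transect
draw_runs <- function(total_length, mean_run, states, probs, min_run = 200) {
  starts <- 0; scores <- sample(states, 1L, prob = probs)
  pos <- max(min_run, stats::rexp(1L, 1 / mean_run))
  while (pos < total_length) {
    prev <- scores[length(scores)]
    w <- probs; w[states == prev] <- 0
    scores <- c(scores, if (sum(w) > 0) sample(states, 1L, prob = w)
                else sample(states, 1L))
    starts <- c(starts, pos)
    pos <- pos + max(min_run, stats::rexp(1L, 1 / mean_run))
  }
  data.frame(start = starts, end = c(starts[-1L], total_length),
             score = scores)
}

#' Generate environmental fields
#'
#' Water visibility is piecewise constant along each transect with
#' exponential run lengths (a continuous-state analogue of a Markov chain
#' over the four visibility categories). Sea state is a slowly varying
#' Beaufort score recorded on a 1 Hz observer GPS track; sun glitter is
#' piecewise constant per platform in `{0..3}`; cloud is one okta value in
#' `{0..8}` per transect.
#'
#' @param config A [survey_config()].
#' @param seed Integer seed.
#' @param mean_run_visibility Mean visibility run length (m).
#' @param visibility_probs Weights over categories 1-4.
#' @param mean_run_glitter Mean glitter run length (m).
#' @param cloud_probs Weights over oktas 0-8.
#' @return List with `visibility` (transect_id, start, end, score),
#'   `track` (time, transect_id, easting, northing, altitude, chainage,
#'   sea_state, glitter), `glitter_imagery` runs, and `cloud`
#'   (transect_id, okta).
#' @export
generate_environment <- function(config, seed = config$seed,
                                 mean_run_visibility = 5000,
                                 visibility_probs = c(0.30, 0.40, 0.25, 0.05),
                                 mean_run_glitter = 8000,
                                 cloud_probs = c(8, rep(0.5, 4), 1, 1, 0.5, 1.5)) {
  set.seed(seed)
  layout <- generate_transect_layout(config)
  vis <- list(); glit <- list(); track <- list()
  t0 <- transect_start_times(config, config$observer_speed)
  for (k in seq_len(nrow(layout))) {
    v <- draw_runs(config$transect_length, mean_run_visibility, 1:4,
                   visibility_probs)
    vis[[k]] <- cbind(transect_id = layout$transect_id[k], v)
    gl <- draw_runs(config$transect_length, mean_run_glitter, 0:3,
                    c(0.4, 0.3, 0.2, 0.1))
    glit[[k]] <- cbind(transect_id = layout$transect_id[k], gl)
    # 1 Hz GPS track with random-walk Beaufort sea state (2-min steps)
    tt <- seq(0, config$transect_length / config$observer_speed, by = 1)
    chain <- tt * config$observer_speed
    n_blocks <- ceiling(length(tt) / 120)
    ss <- numeric(n_blocks); ss[1L] <- sample(0:4, 1L)
    if (n_blocks > 1L) for (b in 2:n_blocks)
      ss[b] <- min(5, max(0, ss[b - 1L] + sample(c(-1, 0, 1), 1L)))
    sea <- ss[ceiling(seq_along(tt) / 120)]
    gl_at <- gl$score[findInterval(pmin(chain, config$transect_length - 1e-9),
                                   gl$start)]
    track[[k]] <- data.frame(
      time = t0[k] + tt, transect_id = layout$transect_id[k],
      easting = layout$easting[k],
      northing = layout$northing_start[k] + chain,
      altitude = config$observer_target_altitude +
        stats::rnorm(length(tt), 0, 3),
      chainage = chain, sea_state = sea, glitter = gl_at)
  }
  list(visibility = do.call(rbind, vis),
       track = do.call(rbind, track),
       glitter_imagery = do.call(rbind, glit),
       cloud = data.frame(transect_id = layout$transect_id,
                          okta = sample(0:8, nrow(layout), replace = TRUE,
                                        prob = cloud_probs)))
}

#' Value of a piecewise-constant run table at given chainages
#'
#' @param runs Run table (`transect_id`, `start`, `end`, `score`).
#' @param transect_id Transect of each query.
#' @param chainage Chainage (m) of each query.
#' @return Scores at the query positions.
#' @export
env_value_at <- function(runs, transect_id, chainage) {
  out <- numeric(length(chainage))
  for (tr in unique(transect_id)) {
    r <- runs[runs$transect_id == tr, ]
    i <- transect_id == tr
    out[i] <- r$score[findInterval(pmax(0, pmin(chainage[i],
                                                max(r$end) - 1e-9)),
                                   r$start)]
  }
  out
}

#' Simulate a complete synthetic survey
#'
#' Runs the whole forward model (layout, groups, telemetry, environment,
#' observer calls, reviewer detections) and optionally writes the
#' canonical file set: `images.csv`, `detections.csv`, `calls.csv`,
#' `track.csv`, `cloud.csv`, `visibility.csv`, `truth_groups.csv`,
#' `truth_members.csv`, `transects.geojson` and `config.yaml`.
#'
#' @param config A [survey_config()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param density Groups per km^2 (scalar or per transect).
#' @param p_observer Per-seat detection probabilities `(front, back)`.
#' @param p_reviewers Per-reviewer detection probabilities.
#' @param n_flights Number of flights; transects are split into contiguous
#'   blocks, one block per flight.
#' @param out_dir Optional directory to write the file set into.
#' @param ... Passed to [generate_groups()].
#' @return List with `config`, `layout`, `truth`, `images`, `footprints`,
#'   `calls`, `detections`, `environment`, `flights` (transect to flight
#'   map).
#' @export
simulate_survey <- function(config, seed = config$seed,
                            density = 0.5,
                            p_observer = c(0.74, 0.81),
                            p_reviewers = c(0.917, 0.979, 0.802),
                            n_flights = 1L, out_dir = NULL, ...) {
  seeds <- derive_seeds(seed, 5L)
  layout <- generate_transect_layout(config)
  truth <- generate_groups(config, density, seed = seeds[1L], ...)
  images <- generate_telemetry(config, seed = seeds[2L])
  footprints <- footprints_from_images(images, config)
  env <- generate_environment(config, seed = seeds[3L])
  calls <- generate_detections(truth, list(platform = "observer",
                                           p = p_observer),
                               config, seed = seeds[4L])
  detections <- generate_detections(truth, list(platform = "imagery",
                                                p = p_reviewers),
                                    config, seed = seeds[5L],
                                    footprints = footprints, images = images)
  flights <- data.frame(
    transect_id = layout$transect_id,
    flight_id = ceiling(seq_len(nrow(layout)) /
                          ceiling(nrow(layout) / n_flights)))
  out <- list(config = config, layout = layout, truth = truth,
              images = images, footprints = footprints, calls = calls,
              detections = detections, environment = env, flights = flights)
  if (!is.null(out_dir)) write_survey(out, out_dir)
  out
}

# deterministic per-stage seeds below 2^31 from one master seed
derive_seeds <- function(seed, n) {
  (as.double(seed) * 48271 + 7919 * seq_len(n)) %% 2147483647
}

write_survey <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$images, file.path(out_dir, "images.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$detections, file.path(out_dir, "detections.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$calls, file.path(out_dir, "calls.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$environment$track, file.path(out_dir, "track.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$environment$cloud, file.path(out_dir, "cloud.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$environment$visibility,
                   file.path(out_dir, "visibility.csv"), row.names = FALSE)
  utils::write.csv(sim$truth$groups, file.path(out_dir, "truth_groups.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth$members, file.path(out_dir, "truth_members.csv"),
                   row.names = FALSE)
  write_transects_geojson(sim$layout, file.path(out_dir, "transects.geojson"))
  write_survey_config(sim$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Write transect centrelines as GeoJSON LineStrings
#'
#' Coordinates are in the local planar metric frame; the CRS is declared
#' in the file's top-level `crs` member.
#'
#' @param layout Output of [generate_transect_layout()].
#' @param path Output file.
#' @export
write_transects_geojson <- function(layout, path) {
  features <- lapply(seq_len(nrow(layout)), function(i) {
    list(type = "Feature",
         properties = list(transect_id = layout$transect_id[i]),
         geometry = list(type = "LineString",
                         coordinates = list(
                           c(layout$easting[i], layout$northing_start[i]),
                           c(layout$easting[i], layout$northing_end[i]))))
  })
  obj <- list(type = "FeatureCollection",
              crs = list(type = "name",
                         properties = list(name = "local-planar-metres")),
              features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
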