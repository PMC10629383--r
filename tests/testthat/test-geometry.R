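test_that("pixel projection matches trigonometric oracles", {
  cam0 <- camera_model(mount_tilt = 0)
  camt <- camera_model(mount_tilt = 11.5)
  centre <- c(3008, 2000)

  # nadir identity
  expect_equal(unname(project_pixel_to_ground(camera_pose(0, 0, 396),
                                              cam0, centre)),
               c(0, 0), tolerance = 1e-12)

  # centre pixel under a tilted mount: offset H * tan(tilt) to starboard
  g <- project_pixel_to_ground(camera_pose(0, 0, 396), camt, centre)
  expect_equal(unname(g[1]), 396 * tan(11.5 * pi / 180), tolerance = 1e-9)
  expect_equal(unname(g[2]), 0, tolerance = 1e-9)

  # across-track swath edges at H = 427: H*tan(tilt -/+ halfFOV)
  half_fov <- atan(0.0116 / 0.050)
  edges <- project_pixel_to_ground(camera_pose(0, 0, 427), camt,
                                   rbind(c(0, 2000), c(6016, 2000)))
  expect_equal(sort(edges[, 1]),
               sort(427 * tan(11.5 * pi / 180 + c(-1, 1) * half_fov)),
               tolerance = 1e-9)

  # horizon / pose errors
  expect_error(project_pixel_to_ground(camera_pose(0, 0, 100),
                                       camera_model(mount_tilt = 80),
                                       c(6016, 2000)), "horizon")
  expect_error(camera_pose(0, 0, -5), "altitude")
})

test_that("footprints match the similar-triangles closed form", {
  cam0 <- camera_model(mount_tilt = 0)
  fp <- image_footprint(camera_pose(0, 0, 396), cam0)
  a_closed <- 396^2 * 0.0232 * 0.0154 / 0.050^2
  expect_equal(poly_area(fp$polygon), a_closed, tolerance = 1e-9)
  expect_gt(poly_signed <- nrow(fp$corners), 3)  # quadrilateral

  # scale equivariance: doubling H doubles every corner offset
  fp2 <- image_footprint(camera_pose(0, 0, 792), cam0)
  expect_equal(fp2$corners, 2 * fp$corners, tolerance = 1e-9)

  # centre GSD, nadir and tilted
  expect_equal(fp$gsd_centre, 396 * (0.0232 / 6016) / 0.050,
               tolerance = 1e-3)
  fpt <- image_footprint(camera_pose(0, 0, 396),
                         camera_model(mount_tilt = 11.5))
  expect_equal(fpt$gsd_centre,
               396 * (0.0232 / 6016) / 0.050 / cos(11.5 * pi / 180)^2,
               tolerance = 1e-3)
})

test_that("azimuth rotation rotates footprints about the nadir point", {
  cam <- camera_model(mount_tilt = 11.5)
  set.seed(31)
  for (i in 1:10) {
    th <- runif(1, 0, 360)
    pose0 <- camera_pose(50, -20, 400, pitch = runif(1, -3, 3),
                         roll = runif(1, -3, 3), azimuth = 0)
    pose1 <- camera_pose(50, -20, 400, pitch = pose0$pitch,
                         roll = pose0$roll, azimuth = th)
    f0 <- image_footprint(pose0, cam)$corners
    f1 <- image_footprint(pose1, cam)$corners
    a <- -th * pi / 180                      # clockwise heading
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    f0r <- sweep(sweep(f0, 2, c(50, -20)) %*% t(R), 2, c(50, -20), "+")
    # same vertex set up to cyclic order
    expect_equal(unname(f0r[order(f0r[, 1], f0r[, 2]), ]),
                 unname(f1[order(f1[, 1], f1[, 2]), ]), tolerance = 1e-8)
  }
})

test_that("forward overlap and capture scheduling are consistent", {
  r <- rect_poly(0, 0, 183.7, 121.97)
  expect_equal(forward_overlap(r, r), 1.0)
  shifted <- r; shifted[, 2] <- shifted[, 2] + 0.6 * 121.97
  expect_equal(forward_overlap(r, shifted), 0.40, tolerance = 1e-9)
  far <- r; far[, 2] <- far[, 2] + 200
  expect_equal(forward_overlap(r, far), 0)

  cfg <- survey_config(drone_altitude = 427)
  dt <- schedule_capture_interval(cfg)
  expect_equal(dt, 427 * 0.0154 / 0.050 * 0.6 / 30.87, tolerance = 1e-12)
  expect_gt(dt, 2); expect_lt(dt, 3)
  # lap = 0 gives full-frame spacing; speed doubling halves the interval
  cfg0 <- survey_config(drone_altitude = 427, target_forward_lap = 0)
  expect_equal(schedule_capture_interval(cfg0), dt / 0.6, tolerance = 1e-12)
  cfg2 <- survey_config(drone_altitude = 427, ground_speed = 2 * 30.87)
  expect_equal(schedule_capture_interval(cfg2), dt / 2, tolerance = 1e-12)

  # scheduled frames from the generator achieve the configured lap
  # (nadir cameras: the interval is set from the nadir along-track length;
  # a tilted camera's slightly longer swath raises the area overlap above
  # the nominal lap, which is a real geometric effect)
  cfg_clean <- survey_config(n_transects = 1, transect_length = 2000,
                             mount_tilt = 0)
  imgs <- generate_telemetry(cfg_clean, sigma_pitch = 0, sigma_roll = 0,
                             sigma_azimuth = 0, sigma_alt = 0)
  fps <- footprints_from_images(imgs[imgs$camera_id == "cam1", ][1:2, ],
                                cfg_clean)
  expect_equal(forward_overlap(fps[[1]], fps[[2]]), 0.40, tolerance = 1e-3)
})

test_that("minimum bounding width uses the rotating-calipers rectangle", {
  r <- rect_poly(0, 0, 200, 150)
  expect_equal(min_bounding_width(r), 200, tolerance = 1e-9)
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(min_bounding_width(r %*% t(R)), 200, tolerance = 1e-9)
  expect_equal(min_bounding_width(rect_poly(5, 5, 100, 100)), 100,
               tolerance = 1e-9)
  # rigid-motion invariance of the minimum rectangle's area (the width
  # can flip between exactly tied minimal rectangles, so the area is the
  # tie-stable invariant; width invariance is covered by the rectangle
  # cases above)
  set.seed(4)
  poly <- cbind(runif(6, 0, 50), runif(6, 0, 50))
  a0 <- min_bounding_rect(poly)$area
  for (i in 1:5) {
    a <- runif(1, 0, 2 * pi)
    Ra <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    expect_equal(min_bounding_rect(sweep(poly %*% t(Ra), 2,
                                         runif(2, -100, 100), "+"))$area,
                 a0, tolerance = 1e-8)
  }
  expect_error(min_bounding_width(rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("observer effective area follows the altitude fraction", {
  cfg <- survey_config()
  expect_equal(observer_effective_area(1000, 152, cfg), 409000)
  expect_equal(observer_effective_area(2000, 160, cfg),
               (160 / 152) * 2000 * 409, tolerance = 1e-12)
  expect_error(observer_effective_area(0, 152, cfg), "length")
})

test_that("observer sightings map to zone centres abeam of the track", {
  cfg <- survey_config()
  track <- data.frame(time = 0:100, easting = 0,
                      northing = (0:100) * 51.44, altitude = 152)
  calls <- data.frame(time = c(10, 10, 20), side = c("port", "starboard",
                                                     "port"),
                      zone = c(0L, 0L, 2L))
  m <- map_observer_sighting(calls, track, cfg)
  expect_equal(m$easting[1], -173)             # gap/2 + 25
  expect_equal(m$easting[2], 173)              # starboard mirror
  expect_equal(m$easting[3], -(148 + 100 + 25))
  expect_equal(m$northing[1], 10 * 51.44)
  # altitude fraction scales the lateral offset
  track$altitude <- 304
  m2 <- map_observer_sighting(calls[1, ], track, cfg)
  expect_equal(m2$easting, -2 * 173)
  expect_error(map_observer_sighting(data.frame(time = 1e6, side = "port",
                                                zone = 0L), track, cfg),
               "time")
})
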