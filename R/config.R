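#' Survey configuration
#'
#' Bundles the fixed design parameters of a paired observer/drone
#' strip-transect survey: transect layout, the observer strip geometry
#' (two lateral strips with a central gap under the aircraft), and the
#' drone imaging system (two obliquely mounted cameras whose combined
#' swath fills the observer gap).
#'
#' Defaults describe a dugong survey design: parallel transects 4.6 km
#' apart; observer strips of 206 m (port) and 203 m (starboard) separated
#' by a 296 m gap at the 152 m target altitude; a two-camera payload
#' (50 mm lens, 23.2 x 15.4 mm sensor, 6016 x 4000 px) tilted +/-11.5
#' degrees from vertical, flown at 396 or 427 m with a 40% target
#' forward-lap at 60 kn (30.87 m/s) ground speed.
#'
#' @param transect_spacing Distance between adjacent transect centrelines (m).
#' @param transect_length Length of each transect (m).
#' @param n_transects Number of parallel transects.
#' @param observer_strip_widths Named or unnamed length-2 numeric,
#'   `(port, starboard)` strip widths at target altitude (m).
#' @param observer_gap Ground-level gap between the two observer strips at
#'   the target altitude (m).
#' @param observer_target_altitude Nominal observer-aircraft altitude (m).
#' @param drone_altitude Nominal drone altitude (m).
#' @param camera_focal_length Lens focal length (m).
#' @param sensor_width,sensor_height Sensor dimensions (m); width is
#'   across-track, height along-track.
#' @param sensor_pixels Length-2 integer `(cols, rows)`.
#' @param mount_tilt Magnitude of each camera's tilt from vertical about the
#'   along-track axis (degrees); the two cameras are tilted in opposite
#'   directions.
#' @param target_forward_lap Prescribed fractional overlap between successive
#'   frames of one camera, in `[0, 1)`.
#' @param ground_speed Drone ground speed (m/s).
#' @param observer_speed Observer-aircraft ground speed (m/s); used for the
#'   GPS track.
#' @param seed Integer seed recorded in the config (generators also accept
#'   explicit seeds).
#' @return An object of class `survey_config` (a validated list).
#' @examples
#' cfg <- survey_config(n_transects = 2, transect_length = 10000)
#' cfg$transect_spacing
#' @export
survey_config <- function(transect_spacing = 4600,
                          transect_length = 40000,
                          n_transects = 2,
                          observer_strip_widths = c(port = 206, starboard = 203),
                          observer_gap = 296,
                          observer_target_altitude = 152,
                          drone_altitude = 396,
                          camera_focal_length = 0.050,
                          sensor_width = 0.0232,
                          sensor_height = 0.0154,
                          sensor_pixels = c(6016L, 4000L),
                          mount_tilt = 11.5,
                          target_forward_lap = 0.40,
                          ground_speed = 30.87,
                          observer_speed = 51.44,
                          seed = 1L) {
  cfg <- list(
    transect_spacing = transect_spacing,
    transect_length = transect_length,
    n_transects = as.integer(n_transects),
    observer_strip_widths = stats::setNames(as.numeric(observer_strip_widths),
                                            c("port", "starboard")),
    observer_gap = observer_gap,
    observer_target_altitude = observer_target_altitude,
    drone_altitude = drone_altitude,
    camera_focal_length = camera_focal_length,
    sensor_width = sensor_width,
    sensor_height = sensor_height,
    sensor_pixels = as.integer(sensor_pixels),
    mount_tilt = mount_tilt,
    target_forward_lap = target_forward_lap,
    ground_speed = ground_speed,
    observer_speed = observer_speed,
    seed = as.integer(seed)
  )
  class(cfg) <- "survey_config"
  validate_survey_config(cfg)
}

validate_survey_config <- function(cfg) {
  lengths_pos <- c("transect_spacing", "transect_length",
                   "observer_gap", "observer_target_altitude",
                   "drone_altitude", "camera_focal_length",
                   "sensor_width", "sensor_height",
                   "ground_speed", "observer_speed")
  for (nm in lengths_pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0)
      stop("survey_config: '", nm, "' must be a single positive number")
  }
  if (cfg$n_transects < 1L)
    stop("survey_config: 'n_transects' must be >= 1")
  if (any(cfg$observer_strip_widths <= 0))
    stop("survey_config: observer strip widths must be > 0")
  if (cfg$target_forward_lap < 0 || cfg$target_forward_lap >= 1)
    stop("survey_config: 'target_forward_lap' must be in [0, 1)")
  if (cfg$mount_tilt < 0 || cfg$mount_tilt >= 45)
    stop("survey_config: 'mount_tilt' must be in [0, 45)")
  if (any(cfg$sensor_pixels < 1L))
    stop("survey_config: 'sensor_pixels' must be positive")
  cfg
}

#' @export
print.survey_config <- function(x, ...) {
  cat("<survey_config>\n")
  cat(sprintf("  %d transect(s) of %.1f km, spaced %.1f km apart\n",
              x$n_transects, x$transect_length / 1000,
              x$transect_spacing / 1000))
  cat(sprintf("  observers: strips %.0f + %.0f m, gap %.0f m, altitude %.0f m\n",
              x$observer_strip_widths[1], x$observer_strip_widths[2],
              x$observer_gap, x$observer_target_altitude))
  cat(sprintf("  drone: %.0f m altitude, %.0f mm lens, tilt +/-%.1f deg, lap %.0f%%\n",
              x$drone_altitude, x$camera_focal_length * 1000, x$mount_tilt,
              100 * x$target_forward_lap))
  invisible(x)
}

#' Read or write a survey configuration as YAML
#'
#' @param path File path.
#' @return `read_survey_config()` returns a `survey_config`;
#'   `write_survey_config()` returns `path` invisibly.
#' @export
read_survey_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(survey_config, vals)
}

#' @rdname read_survey_config
#' @param cfg A `survey_config`.
#' @export
write_survey_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "survey_config"))
  out <- unclass(cfg)
  out$observer_strip_widths <- as.numeric(out$observer_strip_widths)
  yaml::write_yaml(out, path)
  invisible(path)
}
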