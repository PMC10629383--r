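#' Segment a transect by water visibility
#'
#' Transects are split into maximal runs of constant water-visibility
#' score; both platforms share the resulting boundaries. Scores are
#' supplied at points ordered by chainage (in practice, per drone image);
#' boundaries fall midway between the last point of one run and the first
#' point of the next.
#'
#' @param chainage Ordered chainages (m) of the scored points.
#' @param score Visibility category (1-4) at each point.
#' @param transect_length Total transect length (m); defaults to the last
#'   chainage.
#' @return Data frame with `segment_id`, `start`, `end`, `visibility`.
#' @examples
#' segment_by_visibility(c(0, 100, 200, 300), c(1, 1, 2, 2), 400)
#' @export
segment_by_visibility <- function(chainage, score,
                                  transect_length = max(chainage)) {
  if (length(chainage) == 0L) stop("segment_by_visibility: empty input")
  if (is.unsorted(chainage)) stop("segment_by_visibility: unordered chainage")
  r <- rle(score)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- c(1L, utils::head(ends_idx, -1L) + 1L)
  cuts <- if (length(ends_idx) > 1L)
    (chainage[utils::head(ends_idx, -1L)] +
       chainage[utils::head(ends_idx, -1L) + 1L]) / 2
  else numeric(0)
  data.frame(segment_id = seq_along(r$values),
             start = c(0, cuts), end = c(cuts, transect_length),
             visibility = r$values)
}

#' Mean Beaufort sea state within a segment
#'
#' Arithmetic mean of the sea-state scores of the GPS track points whose
#' chainage falls within the segment.
#'
#' @param track Track data frame with `chainage` and `sea_state`.
#' @param start,end Segment bounds (m), `start <= chainage < end` (the
#'   final segment includes its end).
#' @return Mean score, or `NA` with a warning when no point falls inside.
#' @export
mean_sea_state <- function(track, start, end) {
  sel <- track$chainage >= start & track$chainage < end
  if (!any(sel)) {
    warning("mean_sea_state: no track points in segment [", start, ", ",
            end, ")")
    return(NA_real_)
  }
  mean(track$sea_state[sel])
}

#' Mean sun-glitter score within a segment
#'
#' Observer glitter comes from the GPS track records; imagery glitter from
#' the images of the designated sun-side camera only (scores of the other
#' camera are rejected).
#'
#' @param scores Data frame with `chainage`, `score`, and for imagery a
#'   `camera_id` column.
#' @param start,end Segment bounds (m).
#' @param platform `"observer"` or `"imagery"`.
#' @param sun_camera Imagery camera whose frames are scored.
#' @return Mean of the ordinal scores 0-3, or `NA` if none fall inside.
#' @export
mean_glitter <- function(scores, start, end, platform = "observer",
                         sun_camera = "cam1") {
  if (platform == "imagery") {
    if (is.null(scores$camera_id))
      stop("mean_glitter: imagery scores need a camera_id column")
    if (!any(scores$camera_id == sun_camera))
      stop("mean_glitter: no frames from the sun-side camera supplied")
    scores <- scores[scores$camera_id == sun_camera, ]
  }
  sel <- scores$chainage >= start & scores$chainage < end
  if (!any(sel)) return(NA_real_)
  mean(scores$score[sel])
}

#' Binary cloud covariate from okta
#'
#' Any non-zero okta counts as cloud (the threshold is configurable).
#'
#' @param okta Cloud cover in oktas, 0-8.
#' @param threshold Oktas strictly above this count as cloud.
#' @return Integer 0/1 vector.
#' @export
cloud_binary <- function(okta, threshold = 0) {
  if (any(okta < 0 | okta > 8)) stop("cloud_binary: okta outside [0, 8]")
  as.integer(okta > threshold)
}

#' Tally certain, deduplicated sightings within a segment
#'
#' Groups are assigned to the segment containing their centroid chainage;
#' centroids outside all segments snap to the nearest segment (logged via
#' a message).
#'
#' @param segments Segment table for one transect (`start`, `end`).
#' @param groups Group table with `centroid_n` (chainage) and `size`.
#' @return `segments` with added `n_individuals`, `n_groups` and a
#'   `sizes` list-column of the per-group sizes.
#' @export
tally_segment <- function(segments, groups) {
  segments$n_individuals <- 0L
  segments$n_groups <- 0L
  segments$sizes <- vector("list", nrow(segments))
  if (nrow(groups)) {
    idx <- findInterval(groups$centroid_n, segments$start)
    out_of_range <- idx < 1L | groups$centroid_n > max(segments$end)
    if (any(out_of_range))
      message("tally_segment: ", sum(out_of_range),
              " group(s) outside segment range snapped to nearest segment")
    idx <- pmin(pmax(idx, 1L), nrow(segments))
    for (s in seq_len(nrow(segments))) {
      g <- groups[idx == s, , drop = FALSE]
      segments$n_individuals[s] <- sum(g$size)
      segments$n_groups[s] <- nrow(g)
      segments$sizes[[s]] <- g$size
    }
  }
  segments
}

#' Build the segment table for a simulated survey
#'
#' End-to-end segment construction: scores each drone image's
#' mid-footprint chainage against the visibility field, segments every
#' transect, attaches per-platform areas (altitude-corrected strips for
#' observers, dissolved clipped footprint coverage for imagery) and
#' covariates (mean sea state, per-platform mean glitter, okta and binary
#' cloud), then tallies deduplicated certain sightings of both platforms.
#'
#' Missing covariates in short segments are imputed from the nearest
#' scored point on the transect (with a message).
#'
#' @param sim Output of [simulate_survey()].
#' @param observer_groups Observer group table (`transect_id`,
#'   `centroid_n`, `size`), e.g. merged matched calls.
#' @param imagery_groups Imagery group table with the same columns.
#' @return Data frame, one row per segment: identifiers, bounds, length,
#'   visibility, areas (m^2), covariates, and per-platform counts.
#' @export
build_segments <- function(sim, observer_groups, imagery_groups) {
  cfg <- sim$config
  env <- sim$environment
  out <- list()
  for (tr in sim$layout$transect_id) {
    imgs <- sim$images[sim$images$transect_id == tr &
                         sim$images$camera_id == "cam1", ]
    chain <- imgs$northing - sim$layout$northing_start[
      match(tr, sim$layout$transect_id)]
    vis <- env_value_at(env$visibility[env$visibility$transect_id == tr, ],
                        rep(tr, length(chain)), chain)
    seg <- segment_by_visibility(chain, vis, cfg$transect_length)
    seg$transect_id <- tr
    seg$flight_id <- sim$flights$flight_id[match(tr, sim$flights$transect_id)]
    seg$length <- seg$end - seg$start
    track_tr <- env$track[env$track$transect_id == tr, ]
    # imagery glitter scored on the sun-side camera frames
    glit_im <- data.frame(chainage = chain,
                          score = env_value_at(
                            env$glitter_imagery[
                              env$glitter_imagery$transect_id == tr, ],
                            rep(tr, length(chain)), chain),
                          camera_id = "cam1")
    fp_tr <- sim$footprints[sim$images$transect_id == tr]
    seg$mean_sea_state <- NA_real_
    seg$glitter_observer <- NA_real_
    seg$glitter_imagery <- NA_real_
    seg$area_observer <- NA_real_
    origin <- c(sim$layout$easting[match(tr, sim$layout$transect_id)],
                sim$layout$northing_start[match(tr, sim$layout$transect_id)])
    seg$area_imagery <- cut_by_segments(fp_tr,
                                        c(seg$start, seg$end[nrow(seg)]),
                                        origin = origin, heading = 0)
    for (s in seq_len(nrow(seg))) {
      alt <- track_tr$altitude[track_tr$chainage >= seg$start[s] &
                                 track_tr$chainage < seg$end[s]]
      mean_alt <- if (length(alt)) mean(alt) else cfg$observer_target_altitude
      seg$area_observer[s] <- observer_effective_area(seg$length[s],
                                                      mean_alt, cfg)
      seg$mean_sea_state[s] <- suppressWarnings(
        mean_sea_state(track_tr, seg$start[s], seg$end[s]))
      seg$glitter_observer[s] <- mean_glitter(
        data.frame(chainage = track_tr$chainage, score = track_tr$glitter),
        seg$start[s], seg$end[s], platform = "observer")
      seg$glitter_imagery[s] <- mean_glitter(glit_im, seg$start[s],
                                             seg$end[s],
                                             platform = "imagery")
    }
    # nearest-point imputation for covariates missing in short segments
    for (col in c("mean_sea_state", "glitter_observer", "glitter_imagery")) {
      miss <- is.na(seg[[col]])
      if (any(miss) && any(!miss)) {
        message("build_segments: imputing ", sum(miss), " missing ", col,
                " value(s) from nearest segment")
        mid <- (seg$start + seg$end) / 2
        for (s in which(miss))
          seg[[col]][s] <- seg[[col]][!miss][
            which.min(abs(mid[!miss] - mid[s]))]
      }
    }
    seg$cloud_okta <- env$cloud$okta[match(tr, env$cloud$transect_id)]
    seg$cloud_binary <- cloud_binary(seg$cloud_okta)
    seg_obs <- tally_segment(seg, observer_groups[
      observer_groups$transect_id == tr, , drop = FALSE])
    seg_img <- tally_segment(seg, imagery_groups[
      imagery_groups$transect_id == tr, , drop = FALSE])
    seg$count_observer <- seg_obs$n_individuals
    seg$groups_observer <- seg_obs$n_groups
    seg$count_imagery <- seg_img$n_individuals
    seg$groups_imagery <- seg_img$n_groups
    seg$sizes_observer <- seg_obs$sizes
    seg$sizes_imagery <- seg_img$sizes
    out[[length(out) + 1L]] <- seg
  }
  res <- do.call(rbind, out)
  res$segment_uid <- paste0("t", res$transect_id, "s", res$segment_id)
  res
}

#' Reshape a segment table to one row per platform
#'
#' The count models take one observation per segment x platform with that
#' platform's area, glitter and counts.
#'
#' @param segments Output of [build_segments()].
#' @return Long data frame with `platform`, `count`, `n_groups`, `area`,
#'   `glitter` and the shared covariates; `flight_id`, `transect_id` and
#'   `segment_uid` as factors for random effects.
#' @export
segments_long <- function(segments) {
  base <- segments[, c("segment_uid", "flight_id", "transect_id", "length",
                       "visibility", "mean_sea_state", "cloud_okta",
                       "cloud_binary")]
  obs <- cbind(base, platform = "observer",
               count = segments$count_observer,
               n_groups = segments$groups_observer,
               area = segments$area_observer,
               glitter = segments$glitter_observer)
  img <- cbind(base, platform = "imagery",
               count = segments$count_imagery,
               n_groups = segments$groups_imagery,
               area = segments$area_imagery,
               glitter = segments$glitter_imagery)
  long <- rbind(obs, img)
  long$platform <- factor(long$platform, levels = c("observer", "imagery"))
  long$visibility <- factor(long$visibility)
  long$flight_id <- factor(long$flight_id)
  long$transect_id <- factor(paste(long$flight_id, long$transect_id,
                                   sep = ":"))
  rownames(long) <- NULL
  long
}
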