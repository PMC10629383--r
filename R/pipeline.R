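#' @name pipeline
#' @title End-to-end survey pipeline
#'
#' @description
#' Orchestrates simulate -> footprints -> deduplicate -> group -> segment
#' -> perception -> sample-size -> count models as file-mediated stages
#' under one config and master seed, and emits a consolidated report:
#' a per-flight coverage table (area, forward-lap, width, side-lap),
#' per-platform counts and group sizes, the perception estimates, and
#' count-model summaries.
NULL

stage_digest <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Coverage summary per flight
#'
#' For each flight: dissolved covered area, mean forward-lap between
#' consecutive frames of each camera, mean on-ground image width
#' (minimum-bounding-rectangle long side, sampled), and side-lap between
#' the two cameras' coverages.
#'
#' @param sim Output of [simulate_survey()].
#' @param width_sample Number of footprints per flight to measure width
#'   on (widths vary little; sampling keeps the report fast).
#' @return Data frame, one row per flight.
#' @export
coverage_report <- function(sim, width_sample = 50L) {
  imgs <- sim$images
  imgs$flight_id <- sim$flights$flight_id[match(imgs$transect_id,
                                                sim$flights$transect_id)]
  out <- list()
  for (fl in sort(unique(imgs$flight_id))) {
    sel <- which(imgs$flight_id == fl)
    fps <- sim$footprints[sel]
    cam <- imgs$camera_id[sel]
    tr <- imgs$transect_id[sel]
    laps <- c()
    for (t_ in unique(tr)) for (cm in c("cam1", "cam2")) {
      idx <- which(tr == t_ & cam == cm)
      idx <- idx[order(imgs$time[sel][idx])]
      if (length(idx) > 1L)
        laps <- c(laps, vapply(seq_len(length(idx) - 1L), function(i)
          forward_overlap(fps[[idx[i]]], fps[[idx[i + 1L]]]), 0))
    }
    wi <- seq(1L, length(fps), length.out = min(width_sample, length(fps)))
    widths <- vapply(fps[unique(round(wi))], min_bounding_width, 0)
    side <- side_overlap(lapply(fps[cam == "cam1"], fp_poly),
                         lapply(fps[cam == "cam2"], fp_poly))
    out[[length(out) + 1L]] <- data.frame(
      flight_id = fl,
      n_images = length(fps),
      area_km2 = dissolve_coverage(fps)$area / 1e6,
      mean_forward_lap = mean(laps),
      sd_forward_lap = stats::sd(laps),
      mean_width_m = mean(widths),
      side_lap = side)
  }
  do.call(rbind, out)
}

#' Process observer calls into groups and histories
#'
#' Matches front/back calls per side into capture histories, keeps one
#' group per matched history (front-seat size on conflict), maps groups
#' to ground at zone centres and merges groups within the chain
#' threshold.
#'
#' @param calls Observer call table from [generate_detections()].
#' @param track Observer GPS track.
#' @param config A [survey_config()].
#' @param threshold_m Chain-merge threshold (m).
#' @return List with `histories` and `groups` (`transect_id`,
#'   `centroid_e`, `centroid_n`, `size`).
#' @export
process_observer_sightings <- function(calls, track, config,
                                       threshold_m = 200) {
  hist_all <- list(); groups_all <- list()
  for (tr in unique(calls$transect_id)) {
    ct <- calls[calls$transect_id == tr, ]
    h <- match_double_observer(ct[ct$seat == "front", ],
                               ct[ct$seat == "back", ])
    if (!nrow(h)) next
    h$transect_id <- tr
    mapped <- map_observer_sighting(
      data.frame(time = h$time, side = h$side, zone = h$zone),
      track[track$transect_id == tr, ], config)
    h$centroid_e <- mapped$easting
    h$centroid_n <- mapped$northing
    merged <- merge_observer_groups(
      data.frame(centroid_e = h$centroid_e, centroid_n = h$centroid_n,
                 size = h$size), threshold_m)
    merged$transect_id <- tr
    hist_all[[length(hist_all) + 1L]] <- h
    groups_all[[length(groups_all) + 1L]] <- merged
  }
  list(histories = if (length(hist_all)) do.call(rbind, hist_all) else NULL,
       groups = if (length(groups_all)) do.call(rbind, groups_all) else NULL)
}

#' Process imagery detections into individuals and groups
#'
#' Filters to certain detections, deduplicates across overlapping frames
#' (per reviewer for capture histories; for the survey tally a single
#' review pass is emulated with `tally_reviewer`'s detections only),
#' then forms groups by the chain rule.
#'
#' @param detections Imagery detection table.
#' @param footprints Footprint list.
#' @param tally_reviewer Reviewer whose pass supplies the platform tally.
#' @param tolerance_m Dedup ground tolerance (m).
#' @param threshold_m Chain threshold (m).
#' @return List with `individuals` (deduplicated per reviewer),
#'   `groups` (tally groups: `transect_id`, `centroid_e`, `centroid_n`,
#'   `size`) and `per_reviewer` (deduplicated detections, all reviewers).
#' @export
process_imagery_sightings <- function(detections, footprints,
                                      tally_reviewer = 1L,
                                      tolerance_m = 5, threshold_m = 200) {
  det <- detections[detections$certainty == "certain", , drop = FALSE]
  per_rev <- list()
  for (r in sort(unique(det$reviewer_id))) {
    dr <- det[det$reviewer_id == r, , drop = FALSE]
    dd <- deduplicate_imagery(dr, footprints, tolerance_m)
    ind <- stats::aggregate(dd$detections[, c("easting", "northing")],
                            by = list(individual_id =
                                        dd$detections$individual_id), mean)
    ind$reviewer_id <- r
    ind$transect_id <- dd$detections$transect_id[
      match(ind$individual_id, dd$detections$individual_id)]
    per_rev[[length(per_rev) + 1L]] <- ind
  }
  per_rev <- if (length(per_rev)) do.call(rbind, per_rev) else
    data.frame(individual_id = integer(), easting = numeric(),
               northing = numeric(), reviewer_id = integer(),
               transect_id = integer())
  # unique individual ids across reviewers
  if (nrow(per_rev))
    per_rev$individual_id <- paste(per_rev$reviewer_id,
                                   per_rev$individual_id, sep = ".")
  tally <- per_rev[per_rev$reviewer_id == tally_reviewer, , drop = FALSE]
  groups <- NULL
  if (nrow(tally)) {
    gl <- list()
    for (tr in unique(tally$transect_id)) {
      tt <- tally[tally$transect_id == tr, ]
      lab <- chain_group(tt[, c("easting", "northing")], threshold_m)
      g <- do.call(rbind, lapply(unique(lab), function(l) data.frame(
        transect_id = tr, size = sum(lab == l),
        centroid_e = mean(tt$easting[lab == l]),
        centroid_n = mean(tt$northing[lab == l]))))
      gl[[length(gl) + 1L]] <- g
    }
    groups <- do.call(rbind, gl)
  }
  list(individuals = per_rev, groups = groups, per_reviewer = per_rev)
}

#' Run the full pipeline
#'
#' @param config A [survey_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param density Groups per km^2 for the synthetic survey.
#' @param p_observer,p_reviewers True per-occasion probabilities.
#' @param n_flights Flights to split transects into.
#' @param samplesize_reps Replicates for the (deliberately small) demo
#'   precision curve; set 0 to skip.
#' @param ... Passed to [generate_groups()] via [simulate_survey()].
#' @return List with `manifest`, `report` and the stage outputs.
#' @export
run_all <- function(config, out_dir, seed = config$seed, density = 2,
                    p_observer = c(0.74, 0.81),
                    p_reviewers = c(0.917, 0.979, 0.802),
                    n_flights = 2L, samplesize_reps = 50L, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(master_seed = seed, stages = list(),
                   versions = list(
                     skystrip = as.character(utils::packageVersion("skystrip")),
                     R = R.version.string))
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, files, t0) {
    manifest$stages[[name]] <<- list(
      files = stage_digest(file.path(out_dir, files)),
      seconds = round(tic() - t0, 2))
  }

  t0 <- tic()
  sim <- simulate_survey(config, seed = seed, density = density,
                         p_observer = p_observer,
                         p_reviewers = p_reviewers,
                         n_flights = n_flights, out_dir = out_dir, ...)
  stage("simulate", c("images.csv", "detections.csv", "calls.csv",
                      "track.csv", "cloud.csv", "visibility.csv",
                      "truth_groups.csv", "truth_members.csv",
                      "transects.geojson", "config.yaml"), t0)

  t0 <- tic()
  cov <- coverage_report(sim)
  utils::write.csv(cov, file.path(out_dir, "coverage.csv"),
                   row.names = FALSE)
  stage("coverage", "coverage.csv", t0)

  t0 <- tic()
  obs <- process_observer_sightings(sim$calls, sim$environment$track, config)
  img <- process_imagery_sightings(sim$detections, sim$footprints)
  empty_groups <- data.frame(transect_id = integer(), size = integer(),
                             centroid_e = numeric(), centroid_n = numeric())
  og <- obs$groups %||% empty_groups
  ig <- img$groups %||% empty_groups
  utils::write.csv(rbind(cbind(platform = "observer",
                               og[, c("transect_id", "size",
                                      "centroid_e", "centroid_n")]),
                         cbind(platform = "imagery",
                               ig[, c("transect_id", "size",
                                      "centroid_e", "centroid_n")])),
                   file.path(out_dir, "groups.csv"), row.names = FALSE)
  stage("sightings", "groups.csv", t0)

  t0 <- tic()
  segs <- build_segments(sim, og, ig)
  seg_out <- segs[, setdiff(names(segs), c("sizes_observer",
                                           "sizes_imagery"))]
  utils::write.csv(seg_out, file.path(out_dir, "segments.csv"),
                   row.names = FALSE)
  stage("segments", "segments.csv", t0)

  t0 <- tic()
  perception <- list()
  if (!is.null(obs$histories) && nrow(obs$histories) >= 10) {
    sel <- select_model(obs$histories,
                        list(huggins_spec("constant"),
                             huggins_spec("by_occasion"),
                             huggins_spec("by_side"),
                             huggins_spec("saturated")))
    perception$observer <- perception_json(sel)
  }
  rev_hist <- NULL
  if (nrow(img$per_reviewer)) {
    rev_hist <- build_reviewer_histories(
      img$per_reviewer,
      visibility_runs = sim$environment$visibility,
      glitter_runs = sim$environment$glitter_imagery)
    if (nrow(rev_hist) >= 10) {
      sel_r <- select_model(rev_hist,
                            list(huggins_spec("constant"),
                                 huggins_spec("by_occasion"),
                                 huggins_spec("by_occasion", "size_bin")))
      perception$imagery <- perception_json(sel_r)
    }
  }
  jsonlite::write_json(perception, file.path(out_dir, "perception.json"),
                       auto_unbox = TRUE, digits = NA)
  stage("perception", "perception.json", t0)

  t0 <- tic()
  if (samplesize_reps > 0) {
    curve <- run_precision_curve(c(0.7, 0.7), c(25, 100, 500),
                                 n_reps = samplesize_reps,
                                 seed = derive_seeds(seed, 1L))
    utils::write.csv(curve, file.path(out_dir, "scenarios.csv"),
                     row.names = FALSE)
    stage("samplesize", "scenarios.csv", t0)
  }

  t0 <- tic()
  long <- segments_long(segs)
  models <- list()
  if (sum(long$count) > 10) {
    random <- c("flight_id", "transect_id")
    random <- random[vapply(random, function(r)
      length(unique(long[[r]])) > 1L, TRUE)]
    if (!length(random)) random <- NULL
    long$visibility <- droplevels(long$visibility)
    # constant covariates (e.g. no cloud anywhere) are inestimable
    varying <- function(d, covs) covs[vapply(covs, function(v)
      length(unique(d[[v]])) > 1L, TRUE)]
    covs <- varying(long, c("platform", "visibility", "mean_sea_state",
                            "glitter", "cloud_binary"))
    bs_count <- try(backward_select(
      long, stats::reformulate(covs, response = "count"),
      fitter = "tweedie", offset_var = "area", random = random),
      silent = TRUE)
    if (!inherits(bs_count, "try-error"))
      models$individual_counts <- count_model_json(bs_count)
    bs_groups <- try(backward_select(
      long, stats::reformulate(covs, response = "n_groups"),
      fitter = "tweedie", offset_var = "area", random = random),
      silent = TRUE)
    if (!inherits(bs_groups, "try-error"))
      models$group_counts <- count_model_json(bs_groups)
    sizes <- group_size_table(segs)
    if (nrow(sizes) > 20 && any(sizes$size > 1)) {
      covs_s <- varying(sizes, c("platform", "visibility",
                                 "mean_sea_state", "cloud_binary"))
      bs_size <- try(backward_select(
        sizes, stats::reformulate(covs_s, response = "size"),
        fitter = "ztp"), silent = TRUE)
      if (!inherits(bs_size, "try-error"))
        models$group_size <- count_model_json(bs_size)
    }
  }
  jsonlite::write_json(models, file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA)
  stage("count_models", "models.json", t0)

  report <- build_report(out_dir, cov, segs, perception, models)
  manifest$config <- unclass(config)
  manifest$config$observer_strip_widths <-
    as.numeric(manifest$config$observer_strip_widths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, report = report, sim = sim,
                 segments = segs, perception = perception,
                 models = models, coverage = cov))
}

# one row per sighted group with its segment's covariates
group_size_table <- function(segs) {
  rows <- list()
  for (s in seq_len(nrow(segs))) {
    for (pf in c("observer", "imagery")) {
      sizes <- segs[[paste0("sizes_", pf)]][[s]]
      if (length(sizes))
        rows[[length(rows) + 1L]] <- data.frame(
          platform = pf, size = sizes,
          visibility = segs$visibility[s],
          mean_sea_state = segs$mean_sea_state[s],
          cloud_binary = segs$cloud_binary[s],
          flight_id = segs$flight_id[s])
    }
  }
  if (!length(rows))
    return(data.frame(platform = character(), size = integer(),
                      visibility = integer(), mean_sea_state = numeric(),
                      cloud_binary = integer(), flight_id = integer()))
  out <- do.call(rbind, rows)
  out$platform <- factor(out$platform, levels = c("observer", "imagery"))
  out$visibility <- droplevels(factor(out$visibility))
  out
}

perception_json <- function(sel) {
  list(table = sel$table,
       best = list(
         model = sel$table$model[1L],
         p_hat = sel$fits[[1L]]$p_hat,
         se = sel$fits[[1L]]$se,
         p_d = sel$fits[[1L]]$p_d,
         se_d = sel$fits[[1L]]$se_d,
         AICc = sel$fits[[1L]]$AICc))
}

count_model_json <- function(bs) {
  f <- bs$fit
  list(response = f$response, family = f$family, power = f$power,
       phi = f$phi, coefficients = f$coefficients,
       random_sd = as.list(f$random_sd),
       dropped = bs$path, anova = bs$anova)
}

build_report <- function(out_dir, cov, segs, perception, models) {
  report <- list(
    coverage = cov,
    platform_totals = list(
      observer = list(individuals = sum(segs$count_observer),
                      groups = sum(segs$groups_observer),
                      mean_group_size =
                        mean(unlist(segs$sizes_observer))),
      imagery = list(individuals = sum(segs$count_imagery),
                     groups = sum(segs$groups_imagery),
                     mean_group_size = mean(unlist(segs$sizes_imagery)))),
    perception = perception,
    models = models)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  md <- c("# Survey pipeline report", "",
          "## Coverage per flight", "",
          paste(utils::capture.output(print(cov, row.names = FALSE)),
                collapse = "\n"),
          "", "## Platform totals", "",
          sprintf("- observers: %d individuals in %d groups",
                  sum(segs$count_observer), sum(segs$groups_observer)),
          sprintf("- imagery: %d individuals in %d groups",
                  sum(segs$count_imagery), sum(segs$groups_imagery)))
  writeLines(md, file.path(out_dir, "report.md"))
  report
}
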