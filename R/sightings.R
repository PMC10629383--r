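#' Chain-rule grouping of points
#'
#' Partitions points into groups by the 200 m chain rule: two animals
#' belong to the same group if they are connected by a chain of
#' nearest-neighbour links each no longer than the threshold. This is
#' single-linkage clustering cut at the threshold, equivalently the
#' connected components of the graph with edges between points at most
#' `threshold_m` apart (distances at exactly the threshold link).
#'
#' @param points Two-column matrix or data frame of planar coordinates (m).
#' @param threshold_m Chain distance threshold (m).
#' @return Integer vector of group labels (1-based, in order of first
#'   appearance).
#' @examples
#' chain_group(cbind(c(0, 150, 300, 600), 0))  # 1 1 1 2
#' @export
chain_group <- function(points, threshold_m = 200) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::dist(pts), method = "single")
  lab <- stats::cutree(hc, h = threshold_m)
  match(lab, unique(lab))
}

#' Resolve duplicate detections across overlapping frames
#'
#' Detections of the same animal appear once per frame when footprints
#' forward- or side-lap. Two detections in distinct images are linked as
#' one individual when their ground positions are within `tolerance_m`
#' AND both lie inside the overlap region of the two footprints. Links
#' form a forest: each individual is one tree, so
#' `unique + links = raw detections`.
#'
#' @param detections Data frame with `detection_id`, `image_id`,
#'   `easting`, `northing`.
#' @param footprints Named list of `image_footprint`s keyed by `image_id`.
#' @param tolerance_m Ground-distance tolerance (m); default 5 m (about
#'   150 px at a 3.2 cm ground sample distance), a stationary-animal
#'   assumption over the 2-3 s between overlapped frames.
#' @return List with `detections` (input plus `individual_id`), `links`
#'   (data frame of linked detection pairs), `n_unique`, `n_links`.
#' @export
deduplicate_imagery <- function(detections, footprints, tolerance_m = 5) {
  if (tolerance_m < 0) stop("deduplicate_imagery: negative tolerance")
  n <- nrow(detections)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  links <- list()
  if (n > 1L) {
    ee <- detections$easting; nn <- detections$northing
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (detections$image_id[i] == detections$image_id[j]) next
        d <- sqrt((ee[i] - ee[j])^2 + (nn[i] - nn[j])^2)
        if (d > tolerance_m) next
        fa <- footprints[[detections$image_id[i]]]
        fb <- footprints[[detections$image_id[j]]]
        if (is.null(fa) || is.null(fb)) next
        pi_ <- rbind(c(ee[i], nn[i]), c(ee[j], nn[j]))
        in_overlap <- all(points_in_convex(pi_, fa$polygon,
                                           tol = tolerance_m)) &&
          all(points_in_convex(pi_, fb$polygon, tol = tolerance_m))
        if (!in_overlap) next
        ri <- find(i); rj <- find(j)
        if (ri != rj) {
          parent[ri] <- rj
          links[[length(links) + 1L]] <- data.frame(
            detection_a = detections$detection_id[i],
            detection_b = detections$detection_id[j])
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  detections$individual_id <- match(roots, unique(roots))
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(detection_a = integer(), detection_b = integer())
  list(detections = detections, links = links,
       n_unique = length(unique(detections$individual_id)),
       n_links = nrow(links))
}

#' Merge observer groups by the chain rule on centroids
#'
#' Observer groups are plotted at zone-centre points; groups whose
#' plotted centroids chain within the threshold are merged, sizes summed
#' and centroids recomputed as size-weighted means.
#'
#' @param groups Data frame with `centroid_e`, `centroid_n`, `size` (and
#'   any other columns, dropped on merge).
#' @param threshold_m Chain threshold (m).
#' @return Data frame of merged groups (`group_id`, `size`, `centroid_e`,
#'   `centroid_n`, `n_merged`).
#' @export
merge_observer_groups <- function(groups, threshold_m = 200) {
  if (nrow(groups) == 0L)
    return(data.frame(group_id = integer(), size = integer(),
                      centroid_e = numeric(), centroid_n = numeric(),
                      n_merged = integer()))
  lab <- chain_group(groups[, c("centroid_e", "centroid_n")], threshold_m)
  out <- do.call(rbind, lapply(unique(lab), function(l) {
    g <- groups[lab == l, ]
    data.frame(group_id = l, size = sum(g$size),
               centroid_e = sum(g$centroid_e * g$size) / sum(g$size),
               centroid_n = sum(g$centroid_n * g$size) / sum(g$size),
               n_merged = nrow(g))
  }))
  rownames(out) <- NULL
  out
}

#' Match front- and back-seat observer calls into capture histories
#'
#' Greedy one-to-one matching of calls on the same side: candidate pairs
#' must be within `time_window_s` and agree on zone (exactly when
#' `same_zone`, else within one zone). Pairs are matched in order of time
#' difference, ties broken by zone proximity then by earlier front call.
#' Matched pairs give history (1,1) with the front seat's group size
#' (front-seat calls are taken as correct on conflict); unmatched front
#' calls give (1,0), unmatched back calls (0,1).
#'
#' @param front_calls,back_calls Call data frames (`call_id`, `time`,
#'   `side`, `zone`, `size`).
#' @param time_window_s Maximum call-time difference (s).
#' @param same_zone Require exact zone agreement?
#' @return Data frame of capture histories: `y1`, `y2`, `size`, `side`,
#'   `zone`, `time`, plus `front_call_id` / `back_call_id`.
#' @export
match_double_observer <- function(front_calls, back_calls,
                                  time_window_s = 10, same_zone = FALSE) {
  cand <- list()
  if (nrow(front_calls) && nrow(back_calls)) {
    for (i in seq_len(nrow(front_calls))) {
      for (j in seq_len(nrow(back_calls))) {
        if (front_calls$side[i] != back_calls$side[j]) next
        dt <- abs(front_calls$time[i] - back_calls$time[j])
        dz <- abs(front_calls$zone[i] - back_calls$zone[j])
        if (dt > time_window_s) next
        if (same_zone && dz != 0) next
        if (!same_zone && dz > 1) next
        cand[[length(cand) + 1L]] <- data.frame(i = i, j = j, dt = dt,
                                                dz = dz,
                                                tf = front_calls$time[i])
      }
    }
  }
  used_f <- logical(nrow(front_calls)); used_b <- logical(nrow(back_calls))
  pairs <- list()
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$dt, cand$dz, cand$tf), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (used_f[i] || used_b[j]) next
      used_f[i] <- TRUE; used_b[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        y1 = 1L, y2 = 1L, size = front_calls$size[i],
        side = front_calls$side[i], zone = front_calls$zone[i],
        time = front_calls$time[i],
        front_call_id = front_calls$call_id[i],
        back_call_id = back_calls$call_id[j])
    }
  }
  lone <- function(calls, used, which_seat) {
    if (!any(!used)) return(NULL)
    c2 <- calls[!used, , drop = FALSE]
    data.frame(y1 = as.integer(which_seat == "front"),
               y2 = as.integer(which_seat == "back"),
               size = c2$size, side = c2$side, zone = c2$zone,
               time = c2$time,
               front_call_id = if (which_seat == "front") c2$call_id else NA,
               back_call_id = if (which_seat == "back") c2$call_id else NA)
  }
  out <- rbind(if (length(pairs)) do.call(rbind, pairs),
               lone(front_calls, used_f, "front"),
               lone(back_calls, used_b, "back"))
  if (is.null(out))
    out <- data.frame(y1 = integer(), y2 = integer(), size = integer(),
                      side = character(), zone = integer(), time = numeric(),
                      front_call_id = integer(), back_call_id = integer())
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin group sizes for detection covariates
#'
#' @param size Integer group sizes.
#' @return Factor with levels `"1"`, `"2-3"`, `"4+"`.
#' @export
size_bin <- function(size) {
  factor(ifelse(size >= 4, "4+", ifelse(size >= 2, "2-3", "1")),
         levels = c("1", "2-3", "4+"))
}

#' Build three-reviewer capture histories
#'
#' Pools per-reviewer detections of a shared image set, forms groups by
#' the chain rule on the pooled (deduplicated) individual positions, and
#' scores one occasion per reviewer: 1 if that reviewer detected at least
#' one member of the group. Covariates (group-size bin, and visibility /
#' glitter when lookup tables are supplied) are attached per group.
#'
#' @param per_reviewer_detections Data frame of certain, per-reviewer
#'   deduplicated detections: `reviewer_id`, `individual_id`, `easting`,
#'   `northing` (one row per reviewer x individual).
#' @param threshold_m Chain threshold (m).
#' @param visibility_runs,glitter_runs Optional run tables
#'   (see [generate_environment()]) with `transect_id`; detections must
#'   then carry `transect_id` and `northing` is used as chainage.
#' @return Data frame: `group_id`, `y1..yK`, `size`, `size_bin`,
#'   `centroid_e`, `centroid_n` (+ `visibility`, `glitter` if supplied).
#' @export
build_reviewer_histories <- function(per_reviewer_detections,
                                     threshold_m = 200,
                                     visibility_runs = NULL,
                                     glitter_runs = NULL) {
  det <- per_reviewer_detections
  if (nrow(det) == 0L) return(data.frame())
  reviewers <- sort(unique(det$reviewer_id))
  # one pooled row per individual
  ind <- stats::aggregate(det[, c("easting", "northing")],
                          by = list(individual_id = det$individual_id), mean)
  lab <- chain_group(ind[, c("easting", "northing")], threshold_m)
  ind$group <- lab
  det$group <- ind$group[match(det$individual_id, ind$individual_id)]
  rows <- lapply(sort(unique(lab)), function(g) {
    members <- ind[ind$group == g, ]
    h <- vapply(reviewers, function(r)
      as.integer(any(det$reviewer_id == r & det$group == g)), 0L)
    out <- data.frame(group_id = g)
    for (k in seq_along(reviewers)) out[[paste0("y", k)]] <- h[k]
    out$size <- nrow(members)
    out$centroid_e <- mean(members$easting)
    out$centroid_n <- mean(members$northing)
    out
  })
  hist <- do.call(rbind, rows)
  hist$size_bin <- size_bin(hist$size)
  if (!is.null(visibility_runs) || !is.null(glitter_runs)) {
    tr <- det$transect_id[match(hist$group_id, det$group)]
    if (!is.null(visibility_runs))
      hist$visibility <- env_value_at(visibility_runs, tr, hist$centroid_n)
    if (!is.null(glitter_runs))
      hist$glitter <- env_value_at(glitter_runs, tr, hist$centroid_n)
  }
  hist
}
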