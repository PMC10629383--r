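#' @name polygon-utils
#' @title Planar polygon utilities
#'
#' @description
#' Small exact-geometry toolkit used for image-footprint accounting.
#' Polygons are numeric matrices with two columns (easting, northing);
#' vertices are stored without a repeated closing point. Footprints are
#' convex quadrilaterals, so all overlap machinery is built on convex
#' clipping (Sutherland-Hodgman) and the union of many convex polygons is
#' computed exactly by incremental inclusion-exclusion.
NULL

#' Signed and absolute polygon area
#'
#' Shoelace formula. Positive signed area means counter-clockwise
#' orientation.
#'
#' @param poly Two-column numeric matrix of vertices.
#' @return Area in squared input units.
#' @export
poly_area <- function(poly) abs(poly_signed_area(poly))

poly_signed_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

ensure_ccw <- function(poly) {
  if (poly_signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  else poly
}

# Clip a polygon by the half-plane {x : a.x <= b}. Returns a matrix
# (possibly with 0 rows). Standard Sutherland-Hodgman edge step.
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (is.null(n) || n == 0L) return(poly[0L, , drop = FALSE])
  d <- poly %*% a - b
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    di <- d[i]; dj <- d[j]
    if (dj <= 0) out <- rbind(out, poly[j, ])
    if ((di < 0) != (dj < 0) && di != dj) {
      t <- dj / (dj - di)
      out <- rbind(out, poly[j, ] + t * (poly[i, ] - poly[j, ]))
    }
  }
  out
}

#' Intersection of a polygon with a convex polygon
#'
#' Sutherland-Hodgman clipping of `subject` against every edge of the
#' convex polygon `clip`. Exact for convex-convex input (the case needed
#' for camera footprints).
#'
#' @param subject,clip Two-column vertex matrices; `clip` must be convex.
#' @return Vertex matrix of the intersection (0 rows if empty).
#' @export
convex_clip <- function(subject, clip) {
  clip <- ensure_ccw(clip)
  n <- nrow(clip)
  out <- subject
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- clip[j, ] - clip[i, ]
    # inward normal of a CCW edge is (-ey, ex); inside means a.x <= b with
    # a = (ey, -ex), b = a . clip[i, ]
    a <- c(e[2L], -e[1L])
    out <- clip_halfplane(out, a, sum(a * clip[i, ]))
    if (nrow(out) == 0L) break
  }
  out
}

#' Do points fall inside a convex polygon?
#'
#' @param pts Two-column matrix of query points.
#' @param poly Convex polygon vertex matrix.
#' @param tol Edge tolerance in input units (points within `tol` outside an
#'   edge still count as inside).
#' @return Logical vector.
#' @export
points_in_convex <- function(pts, poly, tol = 1e-9) {
  poly <- ensure_ccw(poly)
  pts <- matrix(as.numeric(pts), ncol = 2L)
  n <- nrow(poly)
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- poly[j, ] - poly[i, ]
    a <- c(e[2L], -e[1L])
    d <- pts %*% a - sum(a * poly[i, ])
    inside <- inside & (d <= tol * sqrt(sum(e^2)) + tol)
  }
  as.vector(inside)
}

poly_bbox <- function(poly) {
  c(min(poly[, 1L]), min(poly[, 2L]), max(poly[, 1L]), max(poly[, 2L]))
}

#' Exact union area of convex polygons
#'
#' Computes the area of the union of a set of convex polygons by
#' incremental inclusion-exclusion: all non-empty intersections of each new
#' polygon with previously recorded subset-intersections are accumulated
#' with alternating sign. Exact (up to floating point) for the shallow
#' overlap depths of survey footprints; bounding-box prefiltering keeps the
#' cost near-linear along a transect.
#'
#' @param polys List of convex polygon vertex matrices.
#' @param area_tol Intersections below this area (m^2) are dropped.
#' @return Union area.
#' @export
union_area <- function(polys, area_tol = 1e-9) {
  polys <- Filter(function(p) !is.null(p) && nrow(p) >= 3L &&
                    poly_area(p) > area_tol, polys)
  if (length(polys) == 0L) return(0)
  total <- 0
  # active subset-intersections: polygons, signs, bboxes
  act_poly <- list()
  act_sign <- numeric(0)
  act_bbox <- matrix(numeric(0), ncol = 4L)
  for (i in seq_along(polys)) {
    p <- polys[[i]]
    bb <- poly_bbox(p)
    new_poly <- list(p)
    new_sign <- 1
    if (length(act_poly) > 0L) {
      cand <- which(act_bbox[, 1L] <= bb[3L] & act_bbox[, 3L] >= bb[1L] &
                      act_bbox[, 2L] <= bb[4L] & act_bbox[, 4L] >= bb[2L])
      for (k in cand) {
        inter <- convex_clip(act_poly[[k]], p)
        if (nrow(inter) >= 3L && poly_area(inter) > area_tol) {
          new_poly <- c(new_poly, list(inter))
          new_sign <- c(new_sign, -act_sign[k])
        }
      }
    }
    total <- total + sum(new_sign * vapply(new_poly, poly_area, 0))
    act_poly <- c(act_poly, new_poly)
    act_sign <- c(act_sign, new_sign)
    act_bbox <- rbind(act_bbox, t(vapply(new_poly, poly_bbox, numeric(4L))))
  }
  total
}

#' Intersection area of two coverages
#'
#' Each coverage is a convex polygon or a list of convex polygons (e.g. all
#' footprints of one camera). The intersection area of the two unions is
#' the union area of all pairwise clips.
#'
#' @param cov_a,cov_b Coverage (matrix or list of matrices).
#' @return Intersection area.
#' @export
coverage_intersection_area <- function(cov_a, cov_b) {
  la <- if (is.matrix(cov_a)) list(cov_a) else cov_a
  lb <- if (is.matrix(cov_b)) list(cov_b) else cov_b
  bb_b <- t(vapply(lb, poly_bbox, numeric(4L)))
  pieces <- list()
  for (p in la) {
    bb <- poly_bbox(p)
    cand <- which(bb_b[, 1L] <= bb[3L] & bb_b[, 3L] >= bb[1L] &
                    bb_b[, 2L] <= bb[4L] & bb_b[, 4L] >= bb[2L])
    for (k in cand) {
      inter <- convex_clip(p, lb[[k]])
      if (nrow(inter) >= 3L) pieces <- c(pieces, list(inter))
    }
  }
  union_area(pieces)
}

#' Minimum-area bounding rectangle
#'
#' Rotating calipers over the convex hull: the minimum-area enclosing
#' rectangle has a side collinear with a hull edge. Used to measure the
#' on-ground width of an image footprint as the longer rectangle side.
#'
#' @param poly Polygon vertex matrix (need not be convex).
#' @return List with `width` (longer side), `height` (shorter side),
#'   `angle` (radians of the long side from east) and `area`.
#' @export
min_bounding_rect <- function(poly) {
  pts <- unique(matrix(as.numeric(poly), ncol = 2L))
  if (nrow(pts) < 3L || poly_area(poly) <= 0)
    stop("min_bounding_rect: degenerate polygon")
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  n <- nrow(hull)
  best <- NULL
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len               # edge direction
    v <- c(-u[2L], u[1L])      # normal
    s <- hull %*% u
    t <- hull %*% v
    w <- max(s) - min(s)
    hgt <- max(t) - min(t)
    a <- w * hgt
    if (is.null(best) || a < best$area) {
      long <- max(w, hgt); short <- min(w, hgt)
      ang <- if (w >= hgt) atan2(u[2L], u[1L]) else atan2(v[2L], v[1L])
      best <- list(width = long, height = short, angle = ang, area = a)
    }
  }
  best
}

#' On-ground width of a footprint
#'
#' The longer side of the minimum-area bounding rectangle.
#'
#' @param footprint An `image_footprint` or a polygon matrix.
#' @return Width in metres.
#' @export
min_bounding_width <- function(footprint) {
  poly <- if (inherits(footprint, "image_footprint")) footprint$polygon
          else footprint
  min_bounding_rect(poly)$width
}
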