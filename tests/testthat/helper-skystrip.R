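# Shared fixtures and independent oracles for the test suite.

# Brute-force chain-rule oracle: BFS over the graph with edges wherever
# pairwise distance <= threshold. Independent of hclust/cutree.
bfs_chain_oracle <- function(pts, threshold) {
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  adj <- as.matrix(stats::dist(pts)) <= threshold
  lab <- rep(NA_integer_, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (!is.na(lab[s])) next
    comp <- comp + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(lab[v])) next
      lab[v] <- comp
      queue <- c(queue, which(adj[v, ] & is.na(lab)))
    }
  }
  lab
}

# Monte Carlo union-area oracle over the polygons' joint bounding box
mc_union_area <- function(polys, n = 2e5) {
  bbs <- vapply(polys, function(p) c(min(p[, 1]), min(p[, 2]),
                                     max(p[, 1]), max(p[, 2])), numeric(4))
  lo <- c(min(bbs[1, ]), min(bbs[2, ]))
  hi <- c(max(bbs[3, ]), max(bbs[4, ]))
  pts <- cbind(stats::runif(n, lo[1], hi[1]), stats::runif(n, lo[2], hi[2]))
  inside <- rep(FALSE, n)
  for (p in polys) inside <- inside | skystrip::points_in_convex(pts, p)
  mean(inside) * prod(hi - lo)
}

# closed-form conditional MLE for the 2-occasion double-observer design
closed_form_two_occasion <- function(n10, n01, n11) {
  c(p1 = n11 / (n01 + n11), p2 = n11 / (n10 + n11))
}

# expected per-history Fisher information of the conditional likelihood on
# the probability scale, from the enumerated history distribution
huggins_fisher_info <- function(p_true) {
  T_ <- length(p_true)
  pats <- as.matrix(expand.grid(rep(list(0:1), T_)))[-1, , drop = FALSE]
  pc <- apply(pats, 1, function(w) prod(ifelse(w == 1, p_true, 1 - p_true)))
  pc <- pc / sum(pc)
  ll <- function(p) {
    cond <- apply(pats, 1, function(w)
      prod(ifelse(w == 1, p, 1 - p))) / (1 - prod(1 - p))
    sum(pc * log(cond))
  }
  -numDeriv::hessian(ll, p_true)
}

# small rectangular polygon helper
rect_poly <- function(x0, y0, w, h) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
}

# hand-built truth object with singleton groups at given points, all inside
# the coverage of interest
truth_from_points <- function(pts, transect_id = 1L) {
  n <- nrow(pts)
  structure(list(
    groups = data.frame(group_id = seq_len(n), transect_id = transect_id,
                        centroid_e = pts[, 1], centroid_n = pts[, 2],
                        size = 1L, available_observer = TRUE,
                        available_imagery = TRUE),
    members = data.frame(group_id = seq_len(n), member_id = 1L,
                         easting = pts[, 1], northing = pts[, 2])),
    class = "survey_truth")
}

small_config <- function(...) {
  survey_config(n_transects = 1L, transect_length = 10000, seed = 42L, ...)
}
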