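#' Enumerate minimum-detections simulation scenarios
#'
#' Full cross of ordered per-reviewer detection-probability tuples drawn
#' from the grid 0.4, 0.5, ..., 1.0 (7 values per reviewer; reviewers may
#' share or differ in probability, and order matters) with the detection
#' levels. With the default 8 levels this yields 7^2 * 8 = 392 scenarios
#' for two reviewers and 7^3 * 8 = 2744 for three.
#'
#' @param n_reviewers 2 or 3.
#' @param detection_levels Sorted vector of total-detection counts; the
#'   default spans 5 to 500 with increments growing from 20 to 100.
#' @param p_grid Probability grid per reviewer.
#' @return Data frame with columns `p1..pK` and `n_detections`.
#' @export
enumerate_scenarios <- function(n_reviewers = 2L,
                                detection_levels = c(5, 25, 65, 125, 205,
                                                     300, 400, 500),
                                p_grid = seq(0.4, 1.0, by = 0.1)) {
  if (!length(detection_levels)) stop("enumerate_scenarios: empty levels")
  if (is.unsorted(detection_levels))
    stop("enumerate_scenarios: levels must be sorted")
  args <- c(rep(list(p_grid), n_reviewers), list(detection_levels))
  names(args) <- c(paste0("p", seq_len(n_reviewers)), "n_detections")
  grid <- do.call(expand.grid, args)
  grid[, c(paste0("p", seq_len(n_reviewers)), "n_detections")]
}

# enumerate the 2^T - 1 detected histories and their conditional probs
conditional_history_table <- function(p_true) {
  T_ <- length(p_true)
  pats <- as.matrix(expand.grid(rep(list(0:1), T_)))[-1L, , drop = FALSE]
  colnames(pats) <- paste0("y", seq_len(T_))
  pr <- apply(pats, 1L, function(w) prod(ifelse(w == 1, p_true, 1 - p_true)))
  list(patterns = pats, prob = pr / sum(pr))
}

#' Simulate conditional capture histories
#'
#' Draws exactly `n_detections` histories i.i.d. from the distribution of
#' independent Bernoulli occasions conditioned on at least one detection.
#'
#' @param p_true Per-occasion detection probabilities (not all zero).
#' @param n_detections Number of histories to draw.
#' @param seed Optional seed.
#' @return Data frame of aggregated patterns: `y1..yT` and count `n`.
#' @export
simulate_histories <- function(p_true, n_detections, seed = NULL) {
  if (any(p_true < 0 | p_true > 1))
    stop("simulate_histories: probabilities must be in [0, 1]")
  if (all(p_true == 0))
    stop("simulate_histories: all-zero probabilities, conditioning impossible")
  if (!is.null(seed)) set.seed(seed)
  tab <- conditional_history_table(p_true)
  counts <- as.integer(stats::rmultinom(1L, n_detections, tab$prob))
  out <- as.data.frame(tab$patterns)
  out$n <- counts
  out[out$n > 0L, , drop = FALSE]
}

#' Run one scenario of the precision simulation
#'
#' Repeatedly simulates `n_detections` conditional histories and fits the
#' per-occasion ("saturated" occasion-varying) Huggins model; summarises
#' across converged replicates the mean, SD and CV of each occasion's
#' estimate. Non-converged replicates are excluded and counted; a
#' convergence fraction below 0.5 flags the result unreliable.
#'
#' @param p_true Per-occasion true probabilities.
#' @param n_detections Total detections per replicate.
#' @param n_reps Number of replicates (>= 2).
#' @param seed Master seed; replicate seeds derive from it.
#' @return List of class `scenario_result`: `p_true`, `n_detections`,
#'   `mean_p`, `sd_p`, `cv_p` (per occasion), `cv_mean` (mean over
#'   occasions), `conv_frac`, `unreliable`.
#' @export
run_scenario <- function(p_true, n_detections, n_reps = 1000, seed = 1L) {
  if (n_reps < 2) stop("run_scenario: n_reps must be >= 2")
  T_ <- length(p_true)
  spec <- huggins_spec(if (T_ > 1) "by_occasion" else "constant")
  seeds <- derive_seeds(seed, n_reps)
  est <- matrix(NA_real_, n_reps, T_)
  for (r in seq_len(n_reps)) {
    h <- simulate_histories(p_true, n_detections, seed = seeds[r])
    fit <- try(suppressWarnings(fit_huggins(h, spec,
                                            compute_vcov = FALSE)),
               silent = TRUE)
    if (!inherits(fit, "try-error") && fit$converged)
      est[r, ] <- fit$p_hat
  }
  ok <- stats::complete.cases(est)
  conv <- mean(ok)
  mean_p <- colMeans(est[ok, , drop = FALSE])
  sd_p <- apply(est[ok, , drop = FALSE], 2L, stats::sd)
  cv_p <- ifelse(mean_p > 0, sd_p / mean_p, NA_real_)
  structure(list(p_true = p_true, n_detections = n_detections,
                 n_reps = n_reps, mean_p = mean_p, sd_p = sd_p,
                 cv_p = cv_p, cv_mean = mean(cv_p),
                 conv_frac = conv, unreliable = conv < 0.5),
            class = "scenario_result")
}

#' Run the precision simulation over detection levels
#'
#' @param p_true Per-occasion probabilities.
#' @param detection_levels Vector of total-detection counts.
#' @param n_reps Replicates per level.
#' @param seed Master seed.
#' @return Data frame: one row per level x occasion with `p_true`,
#'   `n_detections`, `occasion`, `mean`, `sd`, `cv`, `cv_mean`,
#'   `conv_frac`.
#' @export
run_precision_curve <- function(p_true, detection_levels, n_reps = 1000,
                                seed = 1L) {
  seeds <- derive_seeds(seed, length(detection_levels))
  rows <- list()
  for (i in seq_along(detection_levels)) {
    res <- run_scenario(p_true, detection_levels[i], n_reps, seeds[i])
    rows[[i]] <- data.frame(
      p_true = paste(p_true, collapse = ","),
      n_detections = detection_levels[i],
      occasion = seq_along(p_true),
      mean = res$mean_p, sd = res$sd_p, cv = res$cv_p,
      cv_mean = res$cv_mean, conv_frac = res$conv_frac)
  }
  do.call(rbind, rows)
}

#' Locate the CV asymptote over detection levels
#'
#' Operational rule for "the CV stops decreasing substantially": the
#' smallest detection level `n` whose CV is within 10% of the total
#' decline of the largest level's CV, i.e.
#' `CV(n) - CV(n_max) <= frac * (CV(n_min) - CV(n_max))`.
#'
#' @param n_detections Detection levels (>= 3).
#' @param cv CV at each level (matched to `n_detections`).
#' @param frac Fraction of the total decline tolerated above the final CV.
#' @return List with `n_asymptote`, `flat` (constant curve) and
#'   `non_asymptotic` (asymptote only reached at the final level).
#' @export
asymptote_summary <- function(n_detections, cv, frac = 0.10) {
  if (length(n_detections) < 3) stop("asymptote_summary: need >= 3 levels")
  ord <- order(n_detections)
  n <- n_detections[ord]; v <- cv[ord]
  if (any(diff(v) > 0.05 * max(abs(v))))
    warning("asymptote_summary: CV curve non-monotone beyond noise")
  total <- v[1L] - v[length(v)]
  if (total <= 0)
    return(list(n_asymptote = n[1L], flat = TRUE, non_asymptotic = FALSE))
  ok <- which((v - v[length(v)]) <= frac * total)
  n_a <- n[min(ok)]
  list(n_asymptote = n_a, flat = FALSE,
       non_asymptotic = n_a == n[length(n)])
}
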