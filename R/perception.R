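#' Specify a Huggins detection-probability model
#'
#' Candidate structures for per-occasion detection probability on the
#' logit scale: constant across occasions, varying by occasion (observer
#' role front/back, or image reviewer), varying by aircraft side, or
#' saturated (occasion x side where a side column exists, otherwise one
#' parameter per occasion). Group-level covariates (`size_bin`,
#' `visibility`, `glitter`) may be added, optionally interacted with
#' occasion.
#'
#' @param structure One of `"constant"`, `"by_occasion"`, `"by_side"`,
#'   `"saturated"`.
#' @param covariates Character subset of history columns to add as main
#'   effects (e.g. `c("size_bin", "visibility", "glitter")`).
#' @param interactions Interact each covariate with occasion?
#' @param name Optional label; defaults to a compact description.
#' @return An object of class `huggins_spec`.
#' @export
huggins_spec <- function(structure = c("constant", "by_occasion", "by_side",
                                       "saturated"),
                         covariates = character(0),
                         interactions = FALSE,
                         name = NULL) {
  structure <- match.arg(structure)
  if (is.null(name)) {
    name <- structure
    if (length(covariates))
      name <- paste0(name, "+", paste(covariates, collapse = "+"),
                     if (interactions) ":occ" else "")
  }
  out <- list(structure = structure, covariates = covariates,
              interactions = interactions, name = name)
  class(out) <- "huggins_spec"
  out
}

history_matrix <- function(histories) {
  ycols <- grep("^y[0-9]+$", names(histories), value = TRUE)
  ycols <- ycols[order(as.integer(sub("y", "", ycols)))]
  y <- as.matrix(histories[, ycols, drop = FALSE])
  storage.mode(y) <- "integer"
  if (any(rowSums(y) == 0))
    stop("huggins: all-zero capture history (data are conditional on >= 1 detection)")
  y
}

# long-format design matrix: one row per history x occasion
huggins_design <- function(histories, spec) {
  y <- history_matrix(histories)
  n <- nrow(y); T_ <- ncol(y)
  long <- data.frame(occasion = factor(rep(seq_len(T_), each = n)))
  if (spec$structure %in% c("by_side", "saturated") &&
      !is.null(histories$side))
    long$side <- factor(rep(histories$side, T_))
  for (cv in spec$covariates)
    long[[cv]] <- rep(histories[[cv]], T_)
  rhs <- switch(spec$structure,
    constant = "1",
    by_occasion = "occasion",
    by_side = if (is.null(long$side))
      stop("huggins_spec 'by_side' needs a side column") else "side",
    saturated = if (is.null(long$side)) "occasion" else "occasion * side")
  if (length(spec$covariates)) {
    cvterms <- if (spec$interactions)
      paste(vapply(spec$covariates,
                   function(cv) paste0(cv, " + occasion:", cv), ""),
            collapse = " + ")
    else paste(spec$covariates, collapse = " + ")
    rhs <- paste(rhs, "+", cvterms)
  }
  fml <- stats::as.formula(paste("~", rhs))
  X <- stats::model.matrix(fml, data = long)
  xlev <- lapply(Filter(is.factor, long), levels)
  list(y = y, X = X, long = long, n = n, T_ = T_, formula = fml,
       xlev = xlev)
}

#' Huggins conditional log-likelihood
#'
#' For capture history `w` over independent occasions with per-occasion
#' probabilities `p_i`, the contribution conditional on at least one
#' detection is
#' `prod_i p_i^{w_i} (1-p_i)^{1-w_i} / (1 - prod_i (1 - p_i))`.
#' Probabilities follow the spec's logit-linear design.
#'
#' @param histories Data frame with occasion columns `y1..yT`, optional
#'   covariates, optional `n` column of pattern counts.
#' @param params Coefficient vector on the logit scale.
#' @param spec A [huggins_spec()].
#' @return Log-likelihood (scalar).
#' @export
huggins_loglik <- function(histories, params, spec = huggins_spec("by_occasion")) {
  d <- huggins_design(histories, spec)
  w <- if (!is.null(histories$n)) histories$n else rep(1, d$n)
  eta <- matrix(d$X %*% params, d$n, d$T_)
  lp <- stats::plogis(eta, log.p = TRUE)        # log p
  lq <- stats::plogis(-eta, log.p = TRUE)       # log(1 - p)
  ll_num <- rowSums(ifelse(d$y == 1L, lp, lq))
  q <- exp(rowSums(lq))                         # P(never detected)
  sum(w * (ll_num - log1p(-q)))
}

huggins_grad <- function(histories, params, spec, design = NULL) {
  d <- design %||% huggins_design(histories, spec)
  w <- if (!is.null(histories$n)) histories$n else rep(1, d$n)
  eta <- matrix(d$X %*% params, d$n, d$T_)
  p <- stats::plogis(eta)
  q <- exp(rowSums(log1p(-p)))
  resid <- d$y - p / (1 - q)                    # d loglik / d eta
  as.numeric(crossprod(d$X, as.numeric(resid) * rep(w, d$T_)))
}

#' Fit a Huggins closed-capture model
#'
#' Maximises the conditional likelihood by quasi-Newton (BFGS) on the
#' logit scale with multiple starts, and reports per-occasion detection
#' probabilities at the reference covariate level, their delta-method
#' standard errors, the combined probability of detection by at least one
#' occasion, and AICc.
#'
#' Boundary fits (any fitted logit beyond `boundary_logit`) are flagged;
#' their variance matrix can be singular and SEs are then `NA`.
#'
#' @param histories Data frame with `y1..yT` columns; optional `n`
#'   (pattern counts), `side`, covariate columns.
#' @param spec A [huggins_spec()].
#' @param starts Numeric vector of common starting values on the logit
#'   scale.
#' @param boundary_logit Flag threshold for boundary estimates.
#' @param compute_vcov Compute the observed-information variance matrix
#'   (numerical hessian)? Disable in tight simulation loops that only
#'   need point estimates.
#' @return Object of class `perception_estimate`: list with `p_hat`, `se`,
#'   `vcov_p`, `p_d`, `se_d`, `coef`, `vcov`, `logLik`, `k`, `n`, `AICc`,
#'   `converged`, `boundary`, `spec`.
#' @examples
#' h <- data.frame(y1 = c(1, 0, 1), y2 = c(0, 1, 1), n = c(5, 10, 40))
#' fit <- fit_huggins(h, huggins_spec("by_occasion"))
#' round(fit$p_hat, 4)  # 0.80, 0.8889
#' @export
fit_huggins <- function(histories, spec = huggins_spec("by_occasion"),
                        starts = c(-1, 0, 1), boundary_logit = 9,
                        compute_vcov = TRUE) {
  d <- huggins_design(histories, spec)
  npar <- ncol(d$X)
  n_hist <- if (!is.null(histories$n)) sum(histories$n) else d$n
  if (n_hist < npar + 2)
    stop("fit_huggins: need at least k + 2 histories")
  nll <- function(b) -huggins_loglik(histories, b, spec)
  gr <- function(b) -huggins_grad(histories, b, spec, design = d)
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(rep(s, npar), nll, gr, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("fit_huggins: optimisation failed for all starts")
  beta <- best$par
  grad_norm <- sqrt(sum(gr(beta)^2))
  boundary <- any(abs(beta) > boundary_logit)
  converged <- best$convergence == 0 && (boundary || grad_norm < 1e-4)
  if (compute_vcov) {
    H <- numDeriv::hessian(nll, beta)
    V <- try(solve(H), silent = TRUE)
    if (inherits(V, "try-error") || any(!is.finite(V)) ||
        any(diag(V) < 0)) {
      V <- matrix(NA_real_, npar, npar)
      boundary <- TRUE
    }
  } else V <- matrix(NA_real_, npar, npar)
  # per-occasion p at the reference covariate level
  ref <- d$long[!duplicated(d$long$occasion), , drop = FALSE]
  ref <- ref[order(ref$occasion), , drop = FALSE]
  for (cv in names(ref)) {
    if (cv == "occasion") next
    if (is.factor(ref[[cv]])) ref[[cv]][] <- levels(ref[[cv]])[1L]
    else ref[[cv]] <- min(d$long[[cv]])
  }
  X0 <- stats::model.matrix(d$formula, ref)
  eta0 <- as.numeric(X0 %*% beta)
  p_hat <- stats::plogis(eta0)
  Gp <- X0 * (p_hat * (1 - p_hat))              # d p / d beta
  vcov_p <- Gp %*% V %*% t(Gp)
  se <- sqrt(pmax(diag(vcov_p), 0))
  p_d <- combined_probability(p_hat)
  se_d <- if (all(is.finite(vcov_p))) delta_se_combined(p_hat, vcov_p)
          else NA_real_
  ll <- -best$value
  out <- list(p_hat = p_hat, se = se, vcov_p = vcov_p,
              p_d = p_d, se_d = se_d,
              coef = beta, vcov = V, logLik = ll, k = npar, n = n_hist,
              AICc = aicc(ll, npar, n_hist),
              converged = converged, boundary = boundary, spec = spec)
  class(out) <- "perception_estimate"
  out
}

#' @export
print.perception_estimate <- function(x, ...) {
  cat("<perception_estimate> ", x$spec$name, "\n", sep = "")
  tab <- data.frame(occasion = seq_along(x$p_hat),
                    p_hat = round(x$p_hat, 4), se = round(x$se, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("combined p_d = %.4f (SE %.4f)\n", x$p_d, x$se_d))
  cat(sprintf("logLik %.3f, k %d, n %d, AICc %.3f%s\n", x$logLik, x$k,
              x$n, x$AICc,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Combined probability of detection by at least one occasion
#'
#' `1 - prod(1 - p_i)`.
#'
#' @param p_vector Per-occasion detection probabilities in `[0, 1]`.
#' @return Scalar probability.
#' @examples
#' combined_probability(c(0.74, 0.81))  # 0.9506
#' @export
combined_probability <- function(p_vector) {
  if (any(p_vector < 0 | p_vector > 1))
    stop("combined_probability: probabilities must be in [0, 1]")
  1 - prod(1 - p_vector)
}

#' Delta-method SE of the combined probability
#'
#' First-order propagation of the estimated covariance of the per-occasion
#' probabilities through the complement product: gradient component `i` is
#' `prod_{j != i} (1 - p_j)`. When only a diagonal of SEs is available,
#' pass `diag(se^2)` (independence is then assumed).
#'
#' @param p_vector Per-occasion probabilities.
#' @param vcov Covariance matrix of `p_vector` (symmetric PSD).
#' @return Standard error of the combined probability.
#' @export
delta_se_combined <- function(p_vector, vcov) {
  k <- length(p_vector)
  vcov <- as.matrix(vcov)
  if (!all(dim(vcov) == k))
    stop("delta_se_combined: vcov dimensions do not match p_vector")
  g <- vapply(seq_len(k), function(i) prod(1 - p_vector[-i]), 0)
  sqrt(max(0, as.numeric(t(g) %*% vcov %*% g)))
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`; infinite (with a
#' warning) when `n <= k + 1`.
#'
#' @param logLik Maximised log-likelihood.
#' @param k Number of parameters.
#' @param n Sample size (number of capture histories).
#' @return AICc value.
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) {
    warning("aicc: n <= k + 1, AICc is infinite")
    return(Inf)
  }
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit and rank candidate Huggins models by AICc
#'
#' @param histories Capture-history data frame.
#' @param candidate_specs List of [huggins_spec()]s.
#' @return List of class `perception_selection`: `fits` (ranked
#'   `perception_estimate`s), `table` (name, k, logLik, AICc, dAICc).
#'   Ties in AICc (< 1e-6) are broken by smaller `k`.
#' @export
select_model <- function(histories, candidate_specs) {
  if (!length(candidate_specs)) stop("select_model: no candidates")
  fits <- list()
  for (spec in candidate_specs) {
    f <- try(fit_huggins(histories, spec), silent = TRUE)
    if (!inherits(f, "try-error")) fits[[spec$name]] <- f
  }
  if (!length(fits)) stop("select_model: all candidate fits failed")
  a <- vapply(fits, function(f) f$AICc, 0)
  k <- vapply(fits, function(f) f$k, 0)
  ord <- order(a + k * 1e-9)     # AICc ascending, near-ties by smaller k
  fits <- fits[ord]
  tab <- data.frame(model = names(fits),
                    k = k[ord], logLik = vapply(fits, function(f) f$logLik, 0),
                    AICc = a[ord], dAICc = a[ord] - min(a))
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab), class = "perception_selection")
}

#' @export
print.perception_selection <- function(x, ...) {
  cat("<perception_selection>\n")
  print(transform(x$table, logLik = round(logLik, 3), AICc = round(AICc, 3),
                  dAICc = round(dAICc, 3)), row.names = FALSE)
  invisible(x)
}
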