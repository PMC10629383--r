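#' @name count-models
#' @title Segment-level count models
#'
#' @description
#' The sample unit for platform comparison is the transect segment. The
#' number of animals (or groups) per segment is modelled as Tweedie
#' distributed (compound Poisson-gamma, variance `mu^power` with
#' `1 < power < 2`) with a log link and `log(area)` offset, to
#' accommodate zeros and the extra-Poisson variation induced by animals
#' forming groups. Flight, and transect nested in flight, enter as
#' random intercepts. Group size (always >= 1) is modelled as
#' zero-truncated Poisson.
NULL

#' Compound Poisson-gamma (Tweedie) random deviates
#'
#' `N ~ Poisson(lambda)`, `Y | N ~ Gamma(N * alpha, scale)`, with
#' `lambda = mu^(2-p) / (phi (2-p))`, `alpha = (2-p)/(p-1)`,
#' `scale = phi (p-1) mu^(p-1)`, so that `E[Y] = mu` and
#' `Var[Y] = phi mu^p`.
#'
#' @param n Number of draws.
#' @param mu Mean (scalar or vector).
#' @param power Variance power in (1, 2).
#' @param phi Dispersion.
#' @return Numeric vector (exact zeros occur with probability
#'   `exp(-lambda)`).
#' @export
rtweedie <- function(n, mu, power, phi = 1) {
  stopifnot(power > 1, power < 2)
  mu <- rep_len(mu, n)
  lambda <- mu^(2 - power) / (phi * (2 - power))
  alpha <- (2 - power) / (power - 1)
  scale <- phi * (power - 1) * mu^(power - 1)
  N <- stats::rpois(n, lambda)
  out <- numeric(n)
  pos <- N > 0
  out[pos] <- stats::rgamma(sum(pos), shape = N[pos] * alpha,
                            scale = scale[pos])
  out
}

fixed_design <- function(formula, data) {
  tt <- stats::terms(formula, data = data)
  X <- stats::model.matrix(tt, data)
  list(terms = tt, X = X, assign = attr(X, "assign"),
       labels = attr(tt, "term.labels"))
}

#' Fit a Tweedie count model with optional random intercepts
#'
#' Quasi-likelihood fit with variance function `V(mu) = mu^power`, log
#' link and a `log(offset)` term. Without random effects this is a
#' direct IRLS quasi-GLM; with random effects the model is fitted by
#' penalised (quasi-)likelihood through random-effect smooths, each
#' random intercept block exchangeable within its level (compound
#' symmetry).
#'
#' @param data Data frame (e.g. from [segments_long()]).
#' @param formula Fixed-effects formula, response on the left (e.g.
#'   `count ~ platform + visibility + mean_sea_state + glitter +
#'   cloud_binary`).
#' @param power Tweedie variance power in (1, 2); `NULL` profiles it on
#'   a grid first (see [profile_power()]).
#' @param offset_var Name of the exposure column entering as
#'   `log(offset_var)`; `NULL` for none.
#' @param random Character vector of grouping-factor column names for
#'   random intercepts (nested factors must already be coded uniquely,
#'   as in [segments_long()]); `NULL` for fixed effects only.
#' @return Object of class `count_model_fit`.
#' @export
fit_tweedie <- function(data, formula, power = NULL, offset_var = "area",
                        random = NULL) {
  resp <- all.vars(formula)[1L]
  if (any(data[[resp]] < 0)) stop("fit_tweedie: negative response")
  if (all(data[[resp]] == 0))
    warning("fit_tweedie: all-zero response, intercept at boundary")
  off <- if (!is.null(offset_var)) log(data[[offset_var]]) else
    rep(0, nrow(data))
  if (!is.null(offset_var) && any(!is.finite(off)))
    stop("fit_tweedie: offsets must be positive")
  if (is.null(power))
    power <- profile_power(data, formula, offset_var = offset_var)$power
  stopifnot(power > 1, power < 2)
  des <- fixed_design(formula, data)
  data$.off <- off
  if (is.null(random)) {
    fit <- stats::glm(stats::update(formula, . ~ . + offset(.off)),
                      data = data,
                      family = statmod::tweedie(var.power = power,
                                                link.power = 0),
                      control = list(epsilon = 1e-10, maxit = 100))
    beta <- stats::coef(fit)
    V <- stats::summary.glm(fit)$cov.scaled
    phi <- stats::summary.glm(fit)$dispersion
    rand_sd <- NULL
  } else {
    re_terms <- paste(sprintf("s(%s, bs = 're')", random), collapse = " + ")
    fml <- stats::update(formula,
                         paste(". ~ . +", re_terms, "+ offset(.off)"))
    for (r in random) data[[r]] <- factor(data[[r]])
    fit <- mgcv::gam(fml, data = data,
                     family = mgcv::Tweedie(p = power, link = "log"),
                     method = "REML")
    np <- ncol(des$X)
    beta <- stats::coef(fit)[seq_len(np)]
    V <- stats::vcov(fit)[seq_len(np), seq_len(np), drop = FALSE]
    phi <- fit$scale
    tmp <- utils::capture.output(vc <- mgcv::gam.vcomp(fit, rescale = TRUE))
    rand_sd <- stats::setNames(vc[grep("^s\\(", rownames(vc)), 1L], random)
  }
  se <- sqrt(diag(V))
  coef_tab <- data.frame(term = names(beta), estimate = as.numeric(beta),
                         se = se, z = as.numeric(beta) / se)
  coef_tab$p <- 2 * stats::pnorm(-abs(coef_tab$z))
  structure(list(response = resp, family = "tweedie", power = power,
                 phi = phi, coefficients = coef_tab, beta = beta, vcov = V,
                 random_sd = rand_sd, formula = formula,
                 offset_var = offset_var, random = random,
                 design = des, fit = fit, n = nrow(data)),
            class = "count_model_fit")
}

#' @export
print.count_model_fit <- function(x, ...) {
  cat(sprintf("<count_model_fit> %s (%s%s), n = %d\n", x$response,
              x$family,
              if (x$family == "tweedie")
                sprintf(", power %.2f, phi %.3f", x$power, x$phi) else "",
              x$n))
  print(transform(x$coefficients, estimate = signif(estimate, 4),
                  se = signif(se, 3), z = round(z, 2), p = signif(p, 3)),
        row.names = FALSE)
  if (!is.null(x$random_sd)) {
    cat("random-intercept SDs:\n")
    print(round(x$random_sd, 4))
  }
  invisible(x)
}

#' Profile the Tweedie variance power
#'
#' Profile likelihood for the variance power: at each grid point the
#' fixed-effects quasi-GLM is refitted (giving the fitted means for that
#' power) and the exact compound Poisson-gamma log density (series
#' evaluation) is maximised over the dispersion. An optimum on the grid
#' edge raises a warning suggesting a wider grid (data close to Poisson
#' or gamma behaviour).
#'
#' @inheritParams fit_tweedie
#' @param grid Candidate powers, a subset of (1, 2).
#' @return List with `power`, `grid`, `loglik` (profile values), `phi`
#'   (profiled dispersion at the optimum) and `edge` (logical).
#' @export
profile_power <- function(data, formula, offset_var = "area",
                          grid = seq(1.1, 1.9, by = 0.05)) {
  stopifnot(all(grid > 1), all(grid < 2))
  resp <- all.vars(formula)[1L]
  y <- data[[resp]]
  data$.off <- if (!is.null(offset_var)) log(data[[offset_var]]) else
    rep(0, nrow(data))
  fml <- stats::update(formula, . ~ . + offset(.off))
  prof <- vapply(grid, function(p) {
    fam <- statmod::tweedie(var.power = p, link.power = 0)
    fit <- stats::glm(fml, data = data, family = fam,
                      control = list(epsilon = 1e-10, maxit = 100))
    mu <- stats::fitted(fit)
    phi0 <- sum((y - mu)^2 / mu^p) / stats::df.residual(fit)
    opt <- stats::optimize(function(lphi)
      sum(mgcv::ldTweedie(y, mu, p = p, phi = exp(lphi))[, 1L]),
      interval = log(phi0) + c(-4, 4), maximum = TRUE)
    c(opt$objective, exp(opt$maximum))
  }, numeric(2L))
  best <- which.max(prof[1L, ])
  edge <- best == 1L || best == length(grid)
  if (edge)
    warning("profile_power: optimum at grid edge (", grid[best],
            "); consider widening the grid")
  list(power = grid[best], grid = grid, loglik = prof[1L, ],
       phi = prof[2L, best], edge = edge)
}

# eta is clamped to avoid exp() overflow on divergent interim steps;
# group-size rates live far below the clamp
ztp_loglik <- function(beta, X, y, off) {
  eta <- pmin(as.numeric(X %*% beta) + off, 30)
  lambda <- exp(eta)
  sum(y * eta - lambda - lfactorial(y) - log1p(-exp(-lambda)))
}

ztp_grad <- function(beta, X, y, off) {
  eta <- pmin(as.numeric(X %*% beta) + off, 30)
  lambda <- exp(eta)
  as.numeric(crossprod(X, y - lambda / (1 - exp(-lambda))))
}

#' Fit a zero-truncated Poisson model
#'
#' Maximum likelihood with log link on the untruncated rate `lambda`;
#' the fitted mean is `lambda / (1 - exp(-lambda))`. Newton/BFGS from a
#' Poisson-GLM start. All-ones responses push `lambda` to the lower
#' boundary and are flagged.
#'
#' @param data Data frame; the response (all values >= 1) is the left side
#'   of `formula`.
#' @param formula Model formula, e.g. `size ~ platform + cloud_binary`.
#' @param offset_var Optional exposure column (log offset), usually
#'   `NULL` for group sizes.
#' @return Object of class `count_model_fit` with `family = "zt_poisson"`.
#' @export
fit_ztp <- function(data, formula, offset_var = NULL) {
  resp <- all.vars(formula)[1L]
  y <- data[[resp]]
  if (any(y < 1)) stop("fit_ztp: all sizes must be >= 1")
  des <- fixed_design(formula, data)
  X <- des$X
  off <- if (!is.null(offset_var)) log(data[[offset_var]]) else
    rep(0, nrow(data))
  start <- stats::coef(stats::glm.fit(X, y, offset = off,
                                      family = stats::poisson()))
  start[!is.finite(start)] <- 0      # rank-deficient designs give NA coefs
  opt <- stats::optim(start, function(b) -ztp_loglik(b, X, y, off),
                      function(b) -ztp_grad(b, X, y, off),
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  beta <- opt$par
  boundary <- all(y == 1)
  if (boundary)
    warning("fit_ztp: all sizes are 1; rate estimate at lower boundary")
  H <- numDeriv::hessian(function(b) -ztp_loglik(b, X, y, off), beta)
  V <- try(solve(H), silent = TRUE)
  if (inherits(V, "try-error") || any(diag(V) < 0))
    V <- matrix(NA_real_, ncol(X), ncol(X))
  se <- sqrt(diag(V))
  coef_tab <- data.frame(term = colnames(X), estimate = as.numeric(beta),
                         se = se, z = as.numeric(beta) / se)
  coef_tab$p <- 2 * stats::pnorm(-abs(coef_tab$z))
  ll <- ztp_loglik(beta, X, y, off)
  structure(list(response = resp, family = "zt_poisson", power = NA,
                 phi = 1, coefficients = coef_tab,
                 beta = stats::setNames(as.numeric(beta), colnames(X)),
                 vcov = V, random_sd = NULL, formula = formula,
                 offset_var = offset_var, random = NULL, design = des,
                 logLik = ll, boundary = boundary, n = nrow(data)),
            class = "count_model_fit")
}

# joint Wald test for every term in the fixed design
term_wald <- function(fit) {
  des <- fit$design
  labs <- des$labels
  if (!length(labs))
    return(data.frame(term = character(), df = integer(),
                      wald = numeric(), p = numeric()))
  out <- data.frame(term = labs, df = NA_integer_, wald = NA_real_,
                    p = NA_real_)
  for (i in seq_along(labs)) {
    idx <- which(des$assign == i)
    b <- fit$beta[idx]
    Vb <- fit$vcov[idx, idx, drop = FALSE]
    w <- try(as.numeric(t(b) %*% solve(Vb) %*% b), silent = TRUE)
    if (inherits(w, "try-error")) next
    out$df[i] <- length(idx)
    out$wald[i] <- w
    out$p[i] <- stats::pchisq(w, length(idx), lower.tail = FALSE)
  }
  out
}

# terms that no remaining higher-order term is built on
removable_terms <- function(terms_obj) {
  labs <- attr(terms_obj, "term.labels")
  ord <- attr(terms_obj, "order")
  vars_of <- strsplit(labs, ":", fixed = TRUE)
  removable <- vapply(seq_along(labs), function(i) {
    !any(vapply(seq_along(labs), function(j) {
      j != i && ord[j] > ord[i] && all(vars_of[[i]] %in% vars_of[[j]])
    }, TRUE))
  }, TRUE)
  labs[removable]
}

#' Backwards selection by Wald tests
#'
#' Starting from the full model, repeatedly drops the least significant
#' removable term (interactions before the main effects they contain,
#' respecting marginality) while its Wald p-value exceeds `alpha`, and
#' refits. Works for both Tweedie and zero-truncated Poisson fits.
#'
#' @param data Data frame.
#' @param formula Full fixed-effects formula.
#' @param fitter One of `"tweedie"` or `"ztp"`.
#' @param alpha Retention threshold.
#' @param ... Passed to [fit_tweedie()] or [fit_ztp()] (`power`,
#'   `offset_var`, `random`, ...).
#' @return List with `fit` (final `count_model_fit`), `path` (data frame
#'   of dropped terms and their p-values), `anova` (Wald table of the
#'   final model).
#' @export
backward_select <- function(data, formula, fitter = c("tweedie", "ztp"),
                            alpha = 0.05, ...) {
  fitter <- match.arg(fitter)
  fit_fun <- if (fitter == "tweedie") fit_tweedie else fit_ztp
  current <- formula
  path <- data.frame(dropped = character(), p = numeric())
  repeat {
    fit <- fit_fun(data, current, ...)
    tw <- term_wald(fit)
    cand <- tw[tw$term %in% removable_terms(fit$design$terms), ]
    cand <- cand[!is.na(cand$p), , drop = FALSE]
    if (!nrow(cand) || max(cand$p) <= alpha) break
    drop_term <- cand$term[which.max(cand$p)]
    path <- rbind(path, data.frame(dropped = drop_term,
                                   p = max(cand$p)))
    remaining <- setdiff(attr(fit$design$terms, "term.labels"), drop_term)
    resp <- all.vars(current)[1L]
    current <- if (length(remaining))
      stats::reformulate(remaining, response = resp)
    else stats::as.formula(paste(resp, "~ 1"))
    if (!length(remaining)) { fit <- fit_fun(data, current, ...); break }
  }
  list(fit = fit, path = path, anova = term_wald(fit))
}

#' Multiplicative effect of a model term
#'
#' For a log-link coefficient `beta`, reports `exp(beta)` and its 95%
#' Wald interval as percentages of the reference level (100% = no
#' effect).
#'
#' @param fit A `count_model_fit`.
#' @param term Coefficient name (as in `fit$coefficients$term`).
#' @return List with `ratio`, `lower`, `upper` (percent).
#' @examples
#' # beta = 0.2927, se = 0.16  ->  134% (98-184%)
#' @export
effect_ratio <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop("effect_ratio: term '", term, "' not in fit")
  b <- fit$coefficients$estimate[i]
  se <- fit$coefficients$se[i]
  list(ratio = 100 * exp(b),
       lower = 100 * exp(b - 1.96 * se),
       upper = 100 * exp(b + 1.96 * se))
}
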