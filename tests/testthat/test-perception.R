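test_that("conditional log-likelihood matches hand and enumeration oracles", {
  spec <- huggins_spec("by_occasion")
  # p = (0.5, 0.5), history (1,0): log(0.25 / 0.75)
  h10 <- data.frame(y1 = 1L, y2 = 0L)
  expect_equal(huggins_loglik(h10, c(0, 0), spec), log(0.25 / 0.75),
               tolerance = 1e-12)
  # p = (1, 1) on a (1,1) history contributes log(1) = 0
  h11 <- data.frame(y1 = 1L, y2 = 1L)
  expect_equal(huggins_loglik(h11, c(20, 20), spec), 0, tolerance = 1e-6)
  expect_error(huggins_loglik(data.frame(y1 = 0L, y2 = 0L), c(0, 0), spec),
               "all-zero")

  # independent enumeration oracle on random parameters/data
  set.seed(12)
  for (i in 1:20) {
    b <- rnorm(2)
    p <- plogis(b)
    n <- c(n10 = sample(1:30, 1), n01 = sample(1:30, 1),
           n11 = sample(1:30, 1))
    cond <- c(p[1] * (1 - p[2]), (1 - p[1]) * p[2], p[1] * p[2]) /
      (1 - (1 - p[1]) * (1 - p[2]))
    expected <- sum(n * log(cond))
    h <- data.frame(y1 = c(1, 0, 1), y2 = c(0, 1, 1), n = n)
    # design maps occasion factor -> (intercept, contrast); convert
    beta <- c(b[1], b[2] - b[1])
    expect_equal(huggins_loglik(h, beta, spec), expected, tolerance = 1e-9)
  }
})

test_that("two-occasion MLE equals the closed-form estimator", {
  set.seed(13)
  for (i in 1:60) {
    n10 <- sample(1:50, 1); n01 <- sample(1:50, 1); n11 <- sample(5:80, 1)
    h <- data.frame(y1 = c(1, 0, 1), y2 = c(0, 1, 1),
                    n = c(n10, n01, n11))
    fit <- fit_huggins(h, huggins_spec("by_occasion"),
                       compute_vcov = FALSE)
    cf <- closed_form_two_occasion(n10, n01, n11)
    expect_equal(unname(fit$p_hat), unname(cf), tolerance = 1e-6)
  }
})

test_that("likelihood is invariant under history-row permutation", {
  set.seed(14)
  h <- simulate_histories(c(0.6, 0.8), 200, seed = 1)
  h_long <- h[rep(seq_len(nrow(h)), h$n), c("y1", "y2")]
  beta <- c(0.3, -0.2)
  l1 <- huggins_loglik(h_long, beta, huggins_spec("by_occasion"))
  perm <- sample(nrow(h_long))
  l2 <- huggins_loglik(h_long[perm, ], beta, huggins_spec("by_occasion"))
  expect_equal(l1, l2, tolerance = 1e-12)
  # aggregated and long forms agree
  expect_equal(huggins_loglik(h, beta, huggins_spec("by_occasion")), l1,
               tolerance = 1e-9)
})

test_that("boundary data flag and combined-probability absorption", {
  h <- data.frame(y1 = rep(1L, 30), y2 = rep(1L, 30))
  fit <- fit_huggins(h, huggins_spec("by_occasion"))
  expect_true(fit$boundary)
  expect_true(all(fit$p_hat > 0.999))

  expect_equal(combined_probability(c(0.74, 0.81)), 0.9506,
               tolerance = 1e-12)
  expect_equal(round(combined_probability(c(0.917, 0.979, 0.802)), 3), 1)
  expect_equal(combined_probability(c(1, 0.3)), 1)
  expect_error(combined_probability(c(1.2)), "probabilities")
})

test_that("delta-method SE matches hand arithmetic", {
  expect_equal(delta_se_combined(c(0.5, 0.5), matrix(0, 2, 2)), 0)
  se <- delta_se_combined(c(0.74, 0.81), diag(c(0.03, 0.03)^2))
  expect_equal(se, sqrt((0.19 * 0.03)^2 + (0.26 * 0.03)^2),
               tolerance = 1e-12)
  # absorption: a certain occasion suppresses the others' gradient
  se2 <- delta_se_combined(c(0.74, 1), diag(c(0.03, 0.02)^2))
  expect_equal(se2, 0.26 * 0.02, tolerance = 1e-12)
  expect_error(delta_se_combined(c(0.5, 0.5), diag(3)), "dimensions")
})

test_that("AICc follows the correction formula", {
  expect_equal(aicc(-20, 2, 50), 40 + 4 + 12 / 47, tolerance = 1e-12)
  expect_equal(aicc(-20, 2, 1e9), 44, tolerance = 1e-6)
  expect_equal(aicc(-20, 0, 50), 40)
  expect_warning(a <- aicc(-20, 5, 6), "infinite")
  expect_true(is.infinite(a))
})

test_that("parameter recovery within 3 SE at n = 300", {
  h <- simulate_histories(c(0.7, 0.9), 300, seed = 11)
  fit <- fit_huggins(h, huggins_spec("by_occasion"))
  expect_true(fit$converged)
  expect_lt(abs(fit$p_hat[1] - 0.7), 3 * fit$se[1])
  expect_lt(abs(fit$p_hat[2] - 0.9), 3 * fit$se[2])
  # 3-occasion recovery at the Table-4-like probabilities
  h3 <- simulate_histories(c(0.917, 0.979, 0.802), 2000, seed = 12)
  f3 <- fit_huggins(h3, huggins_spec("by_occasion"))
  truth <- c(0.917, 0.979, 0.802)
  for (i in 1:3)
    expect_lt(abs(f3$p_hat[i] - truth[i]), 3 * f3$se[i])
})

test_that("sampling-distribution coverage of the 3 SE band is nominal", {
  # scaled-down version of the 95%-coverage invariant: 100 replicates at
  # n = 300 of the capture-history forward model
  ok <- vapply(1:100, function(s) {
    h <- simulate_histories(c(0.7, 0.9), 300, seed = 1000 + s)
    f <- try(fit_huggins(h, huggins_spec("by_occasion")), silent = TRUE)
    if (inherits(f, "try-error")) return(NA)
    all(abs(f$p_hat - c(0.7, 0.9)) < 3 * f$se)
  }, TRUE)
  expect_gte(mean(ok, na.rm = TRUE), 0.95)
})

test_that("model selection ranks the generating structure first", {
  cands <- list(huggins_spec("constant"), huggins_spec("by_occasion"))
  # reviewer-varying truth at Table-4-like p, n = 178
  wins <- vapply(1:40, function(s) {
    h <- simulate_histories(c(0.917, 0.979, 0.802), 178, seed = 300 + s)
    sel <- select_model(h, cands)
    sel$table$model[1] == "by_occasion"
  }, TRUE)
  expect_gte(mean(wins), 0.80)
  # equal-p truth: the constant model usually wins
  wins0 <- vapply(1:40, function(s) {
    h <- simulate_histories(c(0.8, 0.8, 0.8), 178, seed = 600 + s)
    select_model(h, cands)$table$model[1] == "constant"
  }, TRUE)
  expect_gt(mean(wins0), 0.5)
  # single candidate returns itself; ties resolved by smaller k
  sel1 <- select_model(simulate_histories(c(0.8, 0.8), 100, seed = 2),
                       list(huggins_spec("constant")))
  expect_equal(sel1$table$model, "constant")
  expect_error(select_model(data.frame(y1 = 1, y2 = 1), list()),
               "no candidates")
})

test_that("covariate designs estimate occasion p at the reference level", {
  set.seed(15)
  # simulate histories whose p depends on a binary covariate
  n <- 400
  covar <- factor(sample(c("a", "b"), n, TRUE))
  p1 <- ifelse(covar == "a", 0.6, 0.8)
  p2 <- ifelse(covar == "a", 0.7, 0.9)
  y1 <- rbinom(n, 1, p1); y2 <- rbinom(n, 1, p2)
  keep <- y1 + y2 > 0
  h <- data.frame(y1 = y1, y2 = y2, grp = covar)[keep, ]
  fit <- fit_huggins(h, huggins_spec("by_occasion", covariates = "grp"))
  expect_equal(length(fit$p_hat), 2L)
  expect_lt(abs(fit$p_hat[1] - 0.6), 3 * fit$se[1])
  expect_lt(abs(fit$p_hat[2] - 0.7), 3 * fit$se[2])
})
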