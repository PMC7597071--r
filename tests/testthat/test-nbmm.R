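test_that("working response and weights follow the log-link formulas", {
  # perfect fit: working residual vanishes
  zw <- nb_working_response_and_weights(y = 4, eta = log(4), mu = 4,
                                        theta = 2, offset = 1)
  expect_equal(zw$z, log(4) - 1)
  # w = mu * theta / (theta + mu)
  zw2 <- nb_working_response_and_weights(y = 0, eta = log(2), mu = 2, theta = 2)
  expect_equal(zw2$w, 1)
  # Poisson limit: w -> mu
  zw3 <- nb_working_response_and_weights(y = 0, eta = log(3), mu = 3, theta = 1e10)
  expect_equal(zw3$w, 3, tolerance = 1e-9)
})

test_that("Newton dispersion update recovers theta and hits clips", {
  set.seed(21)
  mu <- rep(5, 5000)
  y <- rnbinom(5000, size = 2, mu = mu)
  th <- update_theta_newton(y, mu, theta0 = 1)
  expect_lt(abs(th - 2), 0.2)

  # equidispersed (Poisson) data: likelihood increases in theta, upper clip
  yp <- rpois(5000, 5)
  thp <- update_theta_newton(yp, rep(5, 5000), theta0 = 10)
  grid <- exp(seq(log(1), log(1e5), length.out = 40))
  ll <- vapply(grid, function(t) taxamix:::nb_theta_loglik(t, yp, rep(5, 5000),
                                                           rep(1, 5000)), 0)
  expect_equal(which.max(ll), 40L)  # grid-search oracle agrees: increasing
  expect_equal(thp, 1e5)

  # single zero observation, mu = 1: l(theta) = theta*log(theta/(theta+1))
  # decreases from 0 towards -1, so the maximiser is the lower clip
  # (theta -> 0 concentrates all NB mass at zero)
  lgrid <- exp(seq(log(1e-3), log(1e5), length.out = 50))
  lvals <- lgrid * log(lgrid / (lgrid + 1))
  expect_equal(which.max(lvals), 1L)
  th0 <- suppressWarnings(update_theta_newton(0, 1, theta0 = 1))
  expect_equal(th0, 1e-3, tolerance = 1e-3)
})

test_that("degenerate singleton NBMM matches the direct-likelihood NB oracle", {
  set.seed(31)
  n <- 150
  X <- cbind(`(Intercept)` = 1, group = rbinom(n, 1, 0.5), x = rnorm(n))
  off <- log(runif(n, 5e3, 5e4))
  y <- rnbinom(n, size = 2, mu = exp(off - 8 + 0.5 * X[, 2] + 0.2 * X[, 3]))
  meta <- data.frame(subject = paste0("s", 1:n), group = X[, 2], x = X[, 3],
                     total_reads = exp(off))
  spec <- model_spec(~ group + x, ~ 1 | subject, method = "nb")
  fit <- fit_nbmm(build_design(meta, spec, y))
  ora <- nb_glm_oracle(y, X, off)
  expect_lt(max(abs(fit$coef$count - ora$beta) / abs(ora$beta)), 1e-3)
})

test_that("scaling all totals shifts only the intercept", {
  sim <- simulate_nbmm(sim_truth(n_subjects = 25, seed = 13))
  spec <- model_spec(~ group + time, ~ 1 | subject, method = "nb")
  f1 <- fit_nbmm(build_design(sim$meta, spec, sim$table$counts[, 1]))
  meta2 <- sim$meta
  meta2$total_reads <- meta2$total_reads * 10
  f2 <- fit_nbmm(build_design(meta2, spec, sim$table$counts[, 1]))
  expect_equal(f2$coef$count["(Intercept)"],
               f1$coef$count["(Intercept)"] - log(10), tolerance = 1e-6)
  expect_equal(f2$coef$count[c("group", "time")],
               f1$coef$count[c("group", "time")], tolerance = 1e-6)
})

test_that("all-zero responses and aliased covariates are handled", {
  meta <- toy_meta(5, 3)
  spec <- model_spec(~ group, ~ 1 | subject, method = "nb")
  expect_error(fit_nbmm(build_design(meta, spec, rep(0, 15))), "zero-inflated")

  meta$flat <- 0
  spec2 <- model_spec(~ group + flat, ~ 1 | subject, method = "nb")
  set.seed(2)
  y <- rnbinom(15, size = 2, mu = meta$total_reads / 1000)
  fit <- fit_nbmm(build_design(meta, spec2, y))
  expect_false("flat" %in% names(fit$coef$count))
  expect_true(any(grepl("aliased", fit$warnings)))
})

test_that("non-integer counts warn but fit", {
  meta <- toy_meta(5, 3)
  spec <- model_spec(~ group, ~ 1 | subject, method = "nb")
  set.seed(4)
  y <- rnbinom(15, size = 2, mu = meta$total_reads / 1000) + 0.3
  expect_warning(fit_nbmm(build_design(meta, spec, y)), "non-integer")
})

test_that("random-intercept estimates track the quadrature oracle on small instances", {
  # PQL vs adaptive Gauss-Hermite marginal ML on <= 8 observations
  set.seed(17)
  nfail <- 0
  for (r in 1:5) {
    groups <- factor(rep(1:4, each = 2))
    X <- cbind(`(Intercept)` = 1, x = rep(c(0, 1), 4))
    b <- rnorm(4, 0, 0.5)
    y <- rnbinom(8, size = 2, mu = exp(2 + 0.8 * X[, 2] + b[groups]))
    meta <- data.frame(subject = groups, x = X[, 2], total_reads = 1)
    spec <- model_spec(~ x, ~ 1 | subject, method = "nb",
                       offset_policy = "none")
    fit <- tryCatch(fit_nbmm(build_design(meta, spec, y)), error = function(e) NULL)
    if (is.null(fit)) next
    ora <- nb_ri_marginal_oracle(y, X, rep(0, 8), groups)
    rel <- abs(fit$coef$count[["x"]] - ora$beta[2]) /
      max(abs(ora$beta[2]), 0.1)
    if (rel > 0.10) nfail <- nfail + 1
  }
  expect_lte(nfail, 1)
})
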