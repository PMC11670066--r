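test_that("beta-binomial pmf normalises, hits the single-trial marginal, and
          approaches the binomial as precision grows", {
  # single trial: P(k=1) = mu for any precision
  for (phi in c(0.5, 5, 50))
    expect_equal(betabinom_logpmf(1, 1, 0.3, phi), log(0.3), tolerance = 1e-12)

  # normalisation by enumeration
  for (n in c(1, 3, 5, 10))
    for (mu in c(0.1, 0.3, 0.5, 0.9))
      for (phi in c(0.5, 5, 50))
        expect_equal(sum(exp(betabinom_logpmf(0:n, n, mu, phi))), 1,
                     tolerance = 1e-10)

  # binomial limit
  expect_equal(betabinom_logpmf(0:20, 20, 0.3, 1e6),
               dbinom(0:20, 20, 0.3, log = TRUE), tolerance = 1e-3)

  expect_error(betabinom_logpmf(3, 2, 0.5, 1), "k")
  expect_error(betabinom_logpmf(1, 2, 1.2, 1), "mu")
  expect_error(betabinom_logpmf(1, 2, 0.5, -1), "phi")
})

test_that("design assembly produces the documented columns and scaling", {
  met <- data.frame(colony_id = c("A", "B"), nn_m = c(1.5, 6),
                    density_2m = c(2, 0))
  s <- toy_samples(c("A", "B"), c("n1", "n2"), k = c(50, 20))
  d <- build_design(s, met, spec = model_spec("nn"))
  expect_identical(colnames(d$X), c("(Intercept)", "nn", "night2"))
  expect_equal(d$X[, "nn"], c(1.5, 6))
  expect_equal(d$X[, "night2"], c(0, 1))

  # all releases at minute 1: centred time column is identically zero
  ev <- toy_events(c("A", "B"), c("n1", "n2"), minute = c(1, 1))
  dt <- build_design(s, met, ev, model_spec("nn", time_quadratic = TRUE))
  expect_equal(unname(dt$X[, "n1_time"]), c(0, 0))
  expect_equal(unname(dt$X[, "n2_time"]), c(0, 0))

  # hand-assembled 5-row design with per-night centring and scaling
  met5 <- data.frame(colony_id = sprintf("C%d", 1:5), nn_m = 1:5)
  s5 <- toy_samples(sprintf("C%d", 1:5), c("n1", "n1", "n1", "n2", "n2"),
                    k = rep(10, 5))
  ev5 <- toy_events(sprintf("C%d", 1:5), c("n1", "n1", "n1", "n2", "n2"),
                    minute = c(1, 4, 7, 2, 6))
  d5 <- build_design(s5, met5, ev5, model_spec("nn", time_quadratic = TRUE))
  z1 <- (c(0, 3, 6) - 3) / 3            # night-1 minutes-since-first
  z2 <- (c(1, 5) - 3) / sd(c(1, 5))     # night-2
  expect_equal(unname(d5$X[, "n1_time"]), c(z1, 0, 0), tolerance = 1e-12)
  expect_equal(unname(d5$X[, "n2_time"]), c(0, 0, 0, z2), tolerance = 1e-12)
  expect_equal(unname(d5$X[, "n2_time2"]), c(0, 0, 0, z2^2),
               tolerance = 1e-12)

  expect_error(build_design(toy_samples("Z", "n1", 5), met,
                            spec = model_spec("nn")), "missing covariate")
})

test_that("the optimiser matches a fine grid search on the intercept-only
          model and the AIC identity holds", {
  set.seed(31)
  k <- rbinom(30, 200, rbeta(30, 0.35 * 6, 0.65 * 6))
  X <- matrix(1, 30, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_betabinom_glm(X, k = k, n = rep(200, 30))

  # profile the intercept on a fine grid, optimising phi at each point
  prof <- function(b0) {
    o <- optimize(function(lp) -sum(betabinom_logpmf(k, 200, plogis(b0),
                                                     exp(lp))),
                  c(-3, 8))
    -o$objective
  }
  grid <- seq(fit$coefficients[1] - 0.05, fit$coefficients[1] + 0.05,
              length.out = 201)
  ll <- vapply(grid, prof, numeric(1))
  expect_lt(abs(grid[which.max(ll)] - fit$coefficients[1]), 1e-4)
  expect_gte(fit$log_likelihood + 1e-8, max(ll))

  expect_equal(fit$aic, 2 * 2 - 2 * fit$log_likelihood, tolerance = 1e-12)

  # local-optimality audit on a surrounding 10 x 10 grid
  th <- c(fit$coefficients[1], log(fit$dispersion))
  g1 <- seq(th[1] - 0.1, th[1] + 0.1, length.out = 10)
  g2 <- seq(th[2] - 0.2, th[2] + 0.2, length.out = 10)
  for (a in g1) for (b in g2)
    expect_gte(fit$log_likelihood + 1e-8,
               sum(betabinom_logpmf(k, 200, plogis(a), exp(b))))
})

test_that("without overdispersion the fit converges to the binomial GLM", {
  set.seed(32)
  nn <- runif(40, 0, 15)
  night <- rep(c("n1", "n2"), 20)
  mu <- plogis(-0.8 - 0.15 * nn - 1 * (night == "n2"))
  k <- rbinom(40, 500, mu)  # pure binomial data
  met <- data.frame(colony_id = sprintf("C%d", 1:40), nn_m = nn)
  s <- toy_samples(sprintf("C%d", 1:40), night, k, n = 500)
  d <- build_design(s, met, spec = model_spec("nn"))
  bb <- fit_betabinom_glm(d)
  bi <- fit_binomial_glm(d)
  expect_true(all(abs(bb$coefficients - bi$coefficients) < 1e-2))
  expect_true(bb$converged)
})

test_that("fits agree with glmmTMB on a study-shaped dataset", {
  skip_if_not_installed("glmmTMB")
  fx <- make_study_fixture(seed = 8)
  d <- build_design(fx$samples, fx$metrics, fx$events, model_spec("nn"))
  mine <- fit_betabinom_glm(d)
  dat <- data.frame(
    k = fx$samples$n_fertilized, n = fx$samples$n_scored,
    nn = fx$metrics$nn_m[match(fx$samples$colony_id,
                               fx$metrics$colony_id)],
    night = fx$samples$night)
  tmb <- glmmTMB::glmmTMB(cbind(k, n - k) ~ nn + night,
                          family = glmmTMB::betabinomial(), data = dat)
  expect_equal(unname(mine$coefficients),
               unname(glmmTMB::fixef(tmb)$cond), tolerance = 1e-3)
  expect_equal(mine$log_likelihood, as.numeric(stats::logLik(tmb)),
               tolerance = 1e-5)
  expect_equal(unname(mine$standard_errors),
               unname(sqrt(diag(stats::vcov(tmb)$cond))), tolerance = 5e-3)
})

test_that("the colony random intercept integrates out correctly and reports
          boundary estimates as exactly zero", {
  skip_if_not_installed("glmmTMB")
  fx <- make_study_fixture(seed = 5)
  set.seed(33)
  n_zero <- 0
  for (r in 1:6) {
    s <- simulate_fertilization(fx$colonies, fx$metrics, NULL, fx$params)
    d <- build_design(s, fx$metrics, NULL, model_spec("nn"))
    f <- fit_betabinom_glm(d, random_intercept = TRUE)
    dat <- data.frame(k = s$n_fertilized, n = s$n_scored,
                      nn = fx$metrics$nn_m[match(s$colony_id,
                                                 fx$metrics$colony_id)],
                      night = s$night, colony = s$colony_id)
    tmb <- suppressWarnings(
      glmmTMB::glmmTMB(cbind(k, n - k) ~ nn + night + (1 | colony),
                       family = glmmTMB::betabinomial(), data = dat))
    vtmb <- glmmTMB::VarCorr(tmb)$cond$colony[1, 1]
    # adaptive quadrature should never be beaten by the Laplace fit
    expect_gte(f$log_likelihood + 1e-3, as.numeric(stats::logLik(tmb)))
    # variance estimates agree with glmmTMB up to the quadrature-vs-Laplace
    # approximation difference
    expect_lt(abs(f$random_intercept_variance - vtmb), 0.02 + 0.1 * vtmb)
    if (f$random_intercept_variance == 0) n_zero <- n_zero + 1
    # truth has no colony effect: fixed effects essentially unchanged by
    # the random intercept (identical when the variance sits at zero)
    f0 <- fit_betabinom_glm(d)
    tol <- if (f$random_intercept_variance == 0) 1e-4 else 0.2
    expect_true(all(abs(f$coefficients - f0$coefficients) < tol))
    # both AIC conventions reported for random-intercept fits
    expect_equal(f$aic - f$aic_no_re, 2, tolerance = 1e-12)
  }
  expect_gte(n_zero, 1)  # boundary cases occur and are reported as 0
})

test_that("predictions invert the link and decline with isolation", {
  f <- reference_fit()
  expect_equal(100 * predict_mean(f, data.frame(nn = 0, night = "n1")),
               29.96, tolerance = 1e-2)
  p8 <- predict_mean(f, data.frame(nn = 8, night = "n1"))
  p10 <- predict_mean(f, data.frame(nn = 10, night = "n1"))
  expect_true(p10 < 0.10 && 0.10 < p8)
  expect_equal(predict_mean(f, data.frame(nn = 0, night = "n2")),
               plogis(-1.859), tolerance = 1e-12)
  nn <- seq(0, 20, 0.5)
  pr <- predict_mean(f, data.frame(nn = nn, night = "n1"))
  expect_true(all(diff(pr) < 0))
  expect_error(predict_mean(f, data.frame(night = "n1")), "nn")
})

test_that("model comparison ranks by AIC and prefers the generating metric", {
  fx <- make_study_fixture(seed = 4)
  cmp <- compare_models(list(a = model_spec("nn"), b = model_spec("nn")),
                        fx$samples, fx$metrics)
  expect_equal(cmp$aic[1], cmp$aic[2], tolerance = 1e-6)
  expect_error(compare_models(list(model_spec("nn")), fx$samples,
                              fx$metrics), "two")

  set.seed(9)
  wins <- replicate(50, {
    g <- make_study_fixture(seed = sample.int(2^30, 1))
    s <- simulate_fertilization(g$colonies, g$metrics, NULL, g$params)
    tab <- compare_models(list(nn = model_spec("nn"),
                               density_10 = model_spec("density_10")),
                          s, g$metrics)
    tab$model[1] == "nn"
  })
  expect_gte(sum(wins), 45)  # the true metric wins in >= 90% of datasets
})

test_that("binomial regression recovers night effects in intensity and
          damage comparisons", {
  X <- cbind(`(Intercept)` = 1, night2 = c(0, 1))
  eq <- fit_binomial_glm(X, k = c(12, 12), n = c(26, 26))
  expect_equal(unname(eq$coefficients["night2"]), 0, tolerance = 1e-8)
  expect_gt(eq$p_values["night2"], 0.99)

  f <- fit_binomial_glm(X, k = c(9, 17), n = c(26, 26))
  expect_gt(unname(f$coefficients["night2"]), 0)
  expect_true(is.finite(f$p_values["night2"]))

  # threefold damage-probability ratio, night 1 vs night 2
  set.seed(34)
  k1 <- rbinom(12, 100, 0.30); k2 <- rbinom(12, 100, 0.10)
  Xd <- cbind(`(Intercept)` = 1, night2 = rep(c(0, 1), each = 12))
  fd <- fit_binomial_glm(Xd, k = c(k1, k2), n = rep(100, 24))
  or <- exp(-unname(fd$coefficients["night2"]))
  expect_gt(or, 1.8)  # night-1 odds clearly higher
  expect_lt(fd$p_values["night2"], 0.001)
})
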