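# minimal hand-built mr_fit for arithmetic checks
mk_mr <- function(p1, p2) {
  structure(list(
    coefficients = c("(Intercept)" = qlogis(p1),
                     observer2 = qlogis(p2) - qlogis(p1)),
    vcov = diag(0, 2), loglik = 0, npar = 2, AIC = 0,
    mode = "point", distance = "linear", link = "logit", theta = 0,
    boundary = FALSE, penalized = FALSE, covariates = character(0),
    xlev = list(), basis_cols = "(Intercept)", observer_effect = TRUE,
    n = 1, likelihood = "mr_conditional"), class = "mr_fit")
}

test_that("pooled apex probability follows 1 - (1-p1)(1-p2)", {
  expect_equal(apex_probability(mk_mr(1 - 1e-12, 0.3), 0), 1,
               tolerance = 1e-9)
  expect_equal(apex_probability(mk_mr(0.5, 0.5), 0), 0.75)
  expect_equal(apex_probability(mk_mr(0.8, 0.7), 0), 0.94)
})

test_that("symmetric-count conditional MLE matches the 1-D oracle", {
  # 300 each of (1,0), (0,1), (1,1)
  obs <- observation_table(data.frame(
    transect = "t", distance = 0, size = 1,
    det1 = rep(c(1, 0, 1), each = 300),
    det2 = rep(c(0, 1, 1), each = 300)))
  fit <- fit_mr_conditional(obs, distance = "linear")
  # distance column is constant 0, so only the intercept is estimated
  p_hat <- plogis(fit$coefficients[["(Intercept)"]])

  # independent oracle: maximize the conditional likelihood over a common p
  nll <- function(p) -(600 * log(p * (1 - p)) + 300 * log(p^2) -
                         900 * log(1 - (1 - p)^2))
  p_oracle <- optimize(nll, c(1e-6, 1 - 1e-6))$minimum

  expect_equal(p_oracle, 0.5, tolerance = 1e-4)
  expect_equal(p_hat, p_oracle, tolerance = 1e-4)
})

test_that("degenerate capture histories are flagged, not silently fitted", {
  all_dup <- observation_table(data.frame(
    transect = "t", distance = runif(50, 0, 100), size = 1,
    det1 = 1, det2 = 1))
  expect_warning(fit <- fit_mr_conditional(all_dup), "boundary")
  expect_true(fit$boundary)
  expect_equal(apex_probability(fit, 0), 1, tolerance = 1e-6)

  no_dup <- observation_table(data.frame(
    transect = "t", distance = runif(50, 0, 100), size = 1,
    det1 = rep(c(1, 0), 25), det2 = rep(c(0, 1), 25)))
  expect_error(fit_mr_conditional(no_dup), class = "apexds_boundary_error")
})

test_that("logistic coefficients are recovered within 3 SE", {
  set.seed(201)
  a0 <- 1.5; a1 <- -0.004
  n_pool <- 2000
  x <- runif(n_pool, 0, 400)
  p <- plogis(a0 + a1 * x)
  d1 <- rbinom(n_pool, 1, p)
  d2 <- rbinom(n_pool, 1, p)
  seen <- d1 + d2 >= 1
  obs <- observation_table(data.frame(
    transect = "t", distance = x[seen], size = 1,
    det1 = d1[seen], det2 = d2[seen])[1:600, ])
  fit <- fit_mr_conditional(obs, distance = "linear", link = "logit")
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - a0), 3 * se[1])
  expect_lt(abs(fit$coefficients[["distance"]] - a1), 3 * se[2])
})

test_that("mean apex probability averages correctly under both weightings", {
  # identical covariates: the mean is the single pooled value
  m <- mk_mr(0.6, 0.6)
  obs1 <- observation_table(data.frame(
    transect = "t", distance = c(5, 10), size = 1, det1 = 1, det2 = c(0, 1)))
  r <- mean_apex_probability(m, obs1, theta = 0, weights = "equal")
  expect_equal(r$mean, 1 - 0.4^2)
  expect_equal(r$min, r$max)

  # two detections at pooled 0.5 and ~1, equal weights -> 0.75
  m2 <- structure(list(
    coefficients = c("(Intercept)" = qlogis(1 - sqrt(0.5)), v = 1.0441),
    vcov = diag(0, 2), mode = "point", distance = "linear", link = "logit",
    theta = 0, boundary = FALSE, covariates = "v", xlev = list(),
    basis_cols = c("(Intercept)", "v"), observer_effect = FALSE,
    npar = 2, n = 2, likelihood = "mr_conditional"), class = "mr_fit")
  obs2 <- observation_table(data.frame(
    transect = "t", distance = 0, size = 1, det1 = 1, det2 = c(0, 1),
    v = c(0, 20)))
  r2 <- mean_apex_probability(m2, obs2, theta = 0, weights = "equal")
  expect_equal(r2$mean, 0.75, tolerance = 1e-4)
  expect_equal(r2$min, 0.5, tolerance = 1e-4)

  # HT weighting needs inclusion probabilities
  expect_error(mean_apex_probability(m, obs1, theta = 0, weights = "ht"),
               class = "apexds_validation_error")
  r3 <- mean_apex_probability(m2, obs2, theta = 0, weights = "ht",
                              Pa = c(0.5, 1))
  expect_equal(r3$mean, (2 * 0.5 + 1 * 1) / 3, tolerance = 1e-4)
})

test_that("fitted mean apex probability tracks the generating truth", {
  set.seed(202)
  scn <- scenario_recovery()
  scn$mr_covariate_effects <- list(cover = c("0" = 0, "1-25" = -0.3,
                                             "26-75" = -0.6, "76-100" = -1))
  sim <- simulate_survey(scn, seed = 11)
  ds <- fit_cds(sim$obs, sim$design, "two_piece_normal", abundance = FALSE)
  mr <- fit_mr_conditional(sim$obs, covariates = "cover",
                           distance = "apex_quadratic", link = "log",
                           theta = ds$theta)
  est <- mean_apex_probability(mr, sim$obs, theta = ds$theta,
                               weights = "equal")
  # truth averaged directly over the simulated detections
  eff <- scn$mr_covariate_effects$cover[as.character(sim$obs$cover)]
  q1 <- plogis(scn$apex_logits[1] + eff)
  q2 <- plogis(scn$apex_logits[2] + eff)
  truth <- mean(q1 + q2 - q1 * q2)
  expect_equal(est$mean, truth, tolerance = 0.04)
  expect_lt(est$min, est$max)
})

test_that("shared frailty inflates full-independence detection estimates", {
  set.seed(203)
  a <- 0.5; tau <- 1.5
  infl <- numeric(40)
  for (r in 1:40) {
    stakes <- simulate_stakes(
      n_stakes = 300, observers = 2,
      curves = data.frame(apex_logit = c(a, a), sigma = c(14, 14)),
      tau = tau, tau_sigma = 0, w = 20, seed = 5000 + r)
    dat <- stakes_to_obs(stakes)
    mr <- fit_mr_conditional(dat$obs, mode = "full",
                             distance = "apex_quadratic", link = "log",
                             theta = 0)
    infl[r] <- apex_probability(mr, 0)
  }
  # true marginal pooled apex probability by Gauss-Hermite over the frailty
  m1 <- gh_expect(function(e) plogis(a + e), tau)
  m2 <- gh_expect(function(e) plogis(a + e)^2, tau)
  truth <- 2 * m1 - m2
  expect_gt(mean(infl), truth)   # positively biased apex estimate
})

test_that("apex probability is unbiased at the apex when frailty is absent", {
  set.seed(204)
  p_hat <- numeric(30)
  for (r in 1:30) {
    stakes <- simulate_stakes(
      n_stakes = 300, observers = 2,
      curves = data.frame(apex_logit = c(1.1, 1.1), sigma = c(14, 14)),
      tau = 0, tau_sigma = 0, w = 20, seed = 6000 + r)
    dat <- stakes_to_obs(stakes)
    pi_fit <- fit_mr_conditional(dat$obs, mode = "point",
                                 distance = "apex_quadratic", link = "log",
                                 theta = 0)
    fi_fit <- fit_mr_conditional(dat$obs, mode = "full",
                                 distance = "apex_quadratic", link = "log",
                                 theta = 0)
    # the two modes share one conditional likelihood; they differ only in
    # where the fitted probabilities are trusted
    expect_equal(apex_probability(pi_fit, 0), apex_probability(fi_fit, 0),
                 tolerance = 1e-10)
    p_hat[r] <- apex_probability(pi_fit, 0)
  }
  q <- plogis(1.1)
  truth <- 2 * q - q^2
  mc <- sd(p_hat) / sqrt(length(p_hat))
  expect_lt(abs(mean(p_hat) - truth), 3 * mc + 0.005)
})
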