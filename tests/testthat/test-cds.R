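test_that("half-normal MLE matches a grid-search oracle and recovers sigma", {
  set.seed(101)
  w <- 400
  x <- r_detected_distances(1000, function(x) exp(-x^2 / (2 * 80^2)), w)
  dat <- design_for_distances(x, w)
  fit <- fit_cds(dat$obs, dat$design, "half_normal")

  # independent oracle: 1-D grid search over sigma
  grid <- seq(60, 110, by = 0.1)
  ll <- vapply(grid, function(s) {
    mu <- s * sqrt(2 * pi) * (pnorm(w / s) - 0.5)
    sum(-x^2 / (2 * s^2) - log(mu))
  }, numeric(1))
  s_grid <- grid[which.max(ll)]

  expect_gt(fit$spec$sigma1, 72)
  expect_lt(fit$spec$sigma1, 88)
  expect_equal(fit$spec$sigma1, s_grid, tolerance = 0.005)
})

test_that("flat (uniform) distances drive the half-normal to the flat limit", {
  set.seed(102)
  dat <- design_for_distances(runif(400, 0, 400), 400)
  fit <- suppressWarnings(fit_cds(dat$obs, dat$design, "half_normal"))
  mu <- effective_half_width(fit$spec, w = 400)
  expect_gte(mu, 0.95 * 400)
})

test_that("two-piece normal fit agrees with a coarse grid-search oracle", {
  set.seed(103)
  w <- 600
  g <- function(x) ifelse(x <= 110, exp(-(x - 110)^2 / (2 * 60^2)),
                          exp(-(x - 110)^2 / (2 * 150^2)))
  x <- r_detected_distances(800, g, w)
  dat <- design_for_distances(x, w)
  fit <- fit_cds(dat$obs, dat$design, "two_piece_normal")

  grid <- expand.grid(th = seq(90, 130, by = 2.5),
                      s1 = seq(40, 85, by = 2.5),
                      s2 = seq(110, 190, by = 5))
  ll <- vapply(seq_len(nrow(grid)), function(i) {
    th <- grid$th[i]; s1 <- grid$s1[i]; s2 <- grid$s2[i]
    gg <- ifelse(x <= th, exp(-(x - th)^2 / (2 * s1^2)),
                 exp(-(x - th)^2 / (2 * s2^2)))
    sum(log(gg)) - length(x) * log(mu_closed_form(th, s1, s2, w))
  }, numeric(1))
  best <- grid[which.max(ll), ]

  expect_gt(fit$theta, 95)
  expect_lt(fit$theta, 125)
  expect_lt(abs(fit$theta - best$th), 5)
  expect_gt(fit$loglik, max(ll) - 1e-6)  # MLE at least as good as the grid
})

test_that("Horvitz-Thompson abundance reduces to hand arithmetic", {
  # census limit: certain detection, covered area equals study area
  expect_equal(ht_abundance(c(2, 1, 3), rep(1, 3), A = 10, a = 10)$N, 6)
  # textbook weighted sum
  expect_equal(ht_abundance(c(2, 1), c(0.5, 0.25), A = 10, a = 1)$N, 80)
  expect_warning(ht_abundance(1, 0.005, 1, 1), "below 0.01")
  expect_error(ht_abundance(1, 0, 1, 1), class = "apexds_validation_error")
})

test_that("encounter-rate variance matches the replicate-line formula", {
  tr <- data.frame(transect = c("a", "b", "c"), length_km = c(1, 1, 2))
  design <- survey_design(tr, w = 100, area_km2 = 10)
  obs <- observation_table(data.frame(
    transect = rep(c("a", "b", "c"), times = c(2, 3, 5)),
    distance = 10, size = 1, det1 = 1, det2 = 0))
  er <- encounter_rate_variance(obs, design)
  expect_equal(er$var_rate, 0.046875, tolerance = 1e-12)

  # identical rates across lines give zero dispersion
  obs0 <- observation_table(data.frame(
    transect = rep(c("a", "b", "c"), times = c(2, 2, 4)),
    distance = 10, size = 1, det1 = 1, det2 = 0))
  expect_equal(encounter_rate_variance(obs0, design)$var_rate, 0)

  # doubling effort and counts preserves the rate, scales var(n) by 4
  tr2 <- data.frame(transect = c("a", "b", "c"), length_km = 2 * c(1, 1, 2))
  design2 <- survey_design(tr2, w = 100, area_km2 = 10)
  obs2 <- observation_table(data.frame(
    transect = rep(c("a", "b", "c"), times = 2 * c(2, 3, 5)),
    distance = 10, size = 1, det1 = 1, det2 = 0))
  expect_equal(encounter_rate_variance(obs2, design2)$var_n,
               4 * er$var_n, tolerance = 1e-10)

  tr1 <- data.frame(transect = "a", length_km = 1)
  expect_error(
    encounter_rate_variance(obs0[obs0$transect == "a", ],
                            survey_design(tr1, w = 100, area_km2 = 10)),
    class = "apexds_single_transect_error")
})

test_that("abundance SE combines detection and encounter-rate components", {
  set.seed(104)
  w <- 400
  x <- r_detected_distances(300, function(x) exp(-x^2 / (2 * 90^2)), w)
  dat <- design_for_distances(x, w, area = 50)
  # uneven effort allocation so the between-line component is non-zero
  obs <- as.data.frame(dat$obs)
  obs$transect <- sample(c("t1", "t2"), nrow(obs), replace = TRUE,
                         prob = c(0.3, 0.7))
  dat$obs <- observation_table(obs, w = w)
  fit <- fit_cds(dat$obs, dat$design, "half_normal")
  ab <- fit$abundance
  expect_gt(ab$se_detection, 0)
  expect_gt(ab$se_encounter_rate, 0)
  expect_equal(ab$se, sqrt(ab$se_detection^2 + ab$se_encounter_rate^2))
  expect_equal(ab$N, 50 / dat$design$covered_km2 * sum(1 / ab$Pa))
})

test_that("KS statistic matches hand ECDF arithmetic and is calibrated", {
  expect_equal(apexds:::ks_uniform(c(0.25, 0.5, 0.75))$statistic, 0.25)

  # simulate from the fitted family: p-values should rarely be extreme
  set.seed(105)
  small_p <- 0
  for (r in 1:100) {
    x <- r_detected_distances(500, function(x) exp(-x^2 / (2 * 80^2)), 400)
    dat <- design_for_distances(x, 400)
    fit <- fit_cds(dat$obs, dat$design, "half_normal", abundance = FALSE)
    if (gof_ks(fit)$p.value <= 0.01) small_p <- small_p + 1
  }
  expect_lte(small_p, 5)
})

test_that("KS distinguishes a misfit half-normal from the matching 2PN", {
  set.seed(106)
  g <- function(x) ifelse(x <= 200, exp(-(x - 200)^2 / (2 * 40^2)),
                          exp(-(x - 200)^2 / (2 * 60^2)))
  x <- r_detected_distances(600, g, 400)
  dat <- design_for_distances(x, 400)
  hn <- fit_cds(dat$obs, dat$design, "half_normal", abundance = FALSE)
  tpn <- fit_cds(dat$obs, dat$design, "two_piece_normal", abundance = FALSE)
  expect_gt(gof_ks(hn)$statistic, gof_ks(tpn)$statistic)
})

test_that("AIC ranking follows the formula, breaks ties, guards comparability", {
  mk <- function(loglik, k, lik = "ds_conditional", n = 100)
    list(loglik = loglik, npar = k, AIC = 2 * k - 2 * loglik,
         likelihood = lik, n = n, left_truncation = 0)
  r <- aic_select(list(a = mk(-100, 3), b = mk(-100.5, 2)))
  expect_equal(r$AIC[r$model == "a"], 206)
  expect_equal(attr(r, "best"), "b")

  tie <- aic_select(list(big = mk(-100, 4), small = mk(-101, 3)))
  expect_equal(attr(tie, "best"), "small")   # identical AIC, fewer params

  expect_error(aic_select(list(a = mk(-10, 2), b = mk(-10, 2, "mrds"))),
               class = "apexds_comparability_error")
})

test_that("AIC selects the generating covariate model most of the time", {
  set.seed(107)
  w <- 400
  hits <- 0
  for (r in 1:100) {
    cover <- sample(c("low", "high"), 500, replace = TRUE)
    x <- numeric(500)
    for (lev in c("low", "high")) {
      si <- 80 * exp(0.35 * (lev == "high"))
      idx <- which(cover == lev)
      x[idx] <- r_detected_distances(length(idx),
                                     function(x) exp(-x^2 / (2 * si^2)), w)
    }
    dat <- design_for_distances(x, w)
    obs <- as.data.frame(dat$obs)
    obs$cover <- cover
    obs <- observation_table(obs, w = w)
    null_fit <- fit_cds(obs, dat$design, "half_normal", abundance = FALSE)
    cov_fit <- fit_cds(obs, dat$design, "half_normal", covariates = "cover",
                       abundance = FALSE)
    r2 <- aic_select(list(null = null_fit, cover = cov_fit))
    if (attr(r2, "best") == "cover") hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("fitted inclusion probabilities are invariant to distance units", {
  set.seed(108)
  x <- r_detected_distances(400, function(x) exp(-x^2 / (2 * 80^2)), 400)
  d1 <- design_for_distances(x, 400)
  f1 <- fit_cds(d1$obs, d1$design, "half_normal", abundance = FALSE)
  d2 <- design_for_distances(x * 10, 4000)   # same survey in decimetres
  f2 <- fit_cds(d2$obs, d2$design, "half_normal", abundance = FALSE)
  expect_equal(f2$spec$sigma1, 10 * f1$spec$sigma1, tolerance = 1e-4)
  expect_equal(apexds:::fitted_mu(f2)$Pa, apexds:::fitted_mu(f1)$Pa,
               tolerance = 1e-6)
})

test_that("left truncation shifts the half-normal and can target the apex", {
  set.seed(109)
  g <- function(x) ifelse(x <= 110, exp(-(x - 110)^2 / (2 * 60^2)),
                          exp(-(x - 110)^2 / (2 * 150^2)))
  x <- r_detected_distances(700, g, 600)
  dat <- design_for_distances(x, 600)
  fit <- fit_cds(dat$obs, dat$design, "half_normal", left_truncation = "apex")
  expect_gt(fit$left_truncation, 80)
  expect_lt(fit$left_truncation, 140)
  expect_equal(fit$n, sum(x >= fit$left_truncation))
  # the truncated fit should resemble the far-side scale, not the mixture
  expect_gt(fit$spec$sigma1, 100)
  expect_error(fit_cds(dat$obs, dat$design, "two_piece_normal",
                       left_truncation = 50),
               class = "apexds_validation_error")
})

test_that("too little data is refused, small samples warn", {
  dat <- design_for_distances(c(10, 10, 10), 100)
  expect_error(fit_cds(dat$obs, dat$design, "half_normal"),
               class = "apexds_insufficient_data")
  dat2 <- design_for_distances(c(5, 15, 30, 44, 60), 100)
  expect_warning(fit_cds(dat2$obs, dat2$design, "half_normal"),
                 "60-80")
})
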