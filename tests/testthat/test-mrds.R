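test_that("with certain apex detection the MR scaling collapses to CDS", {
  # one observer detects everything at the apex; the pooled correction
  # tends to 1 and the MRDS abundance matches the conventional estimate
  stakes <- simulate_stakes(
    n_stakes = 1500, observers = 2,
    curves = data.frame(apex_logit = c(30, qlogis(0.15)), sigma = c(14, 14)),
    tau = 0, tau_sigma = 0, w = 20, seed = 301)
  dat <- stakes_to_obs(stakes)
  cds <- suppressWarnings(fit_cds(dat$obs, dat$design, "half_normal"))
  pi_fit <- suppressWarnings(
    fit_mrds(dat$obs, dat$design, "half_normal", independence = "point",
             observer_effect = TRUE))
  expect_gt(pi_fit$mr_p$mean, 0.99)
  expect_lt(abs(pi_fit$abundance$N - cds$abundance$N) / cds$abundance$N,
            0.01)
})

test_that("known inclusion probabilities give exact HT arithmetic", {
  # estimation bypassed: plug Pa into the HT sum by hand
  expect_equal(ht_abundance(size = c(2, 1, 4), Pa = c(0.5, 0.2, 0.8),
                            A = 30, a = 3)$N,
               10 * (2 / 0.5 + 1 / 0.2 + 4 / 0.8))
})

test_that("parameters are recovered within 3 SE on a large survey", {
  scn <- scenario_recovery()
  sim <- simulate_survey(scn, seed = 302)
  fit <- fit_mrds(sim$obs, sim$design, "two_piece_normal",
                  independence = "point")
  # theta on the working logistic scale
  w <- sim$design$w
  u_hat <- fit$shape$par[1]
  se_u <- sqrt(fit$shape$vcov[1, 1])
  se_theta <- se_u * w * plogis(u_hat) * (1 - plogis(u_hat))
  expect_lt(abs(fit$theta - scn$theta), 3 * se_theta)
  # sigma1, sigma2 on the log scale
  for (k in 2:3) {
    truth <- log(c(NA, scn$sigma1, scn$sigma2)[k])
    expect_lt(abs(fit$shape$par[k] - truth), 3 * sqrt(fit$shape$vcov[k, k]))
  }
  # MR apex level: log link intercept estimates log q
  a_hat <- fit$mr$coefficients[["(Intercept)"]]
  expect_lt(abs(a_hat - log(plogis(scn$apex_logits[1]))),
            3 * sqrt(fit$mr$vcov[1, 1]))
  expect_equal(fit$mr_p$mean, 0.9, tolerance = 0.05)
})

test_that("truncation fractions match hand counts and the analytic share", {
  obs <- observation_table(data.frame(
    transect = "t", distance = c(50, 120, 200), size = 1, det1 = 1,
    det2 = 0))
  expect_equal(truncation_fraction(obs, 0)$percent, 0)
  expect_equal(truncation_fraction(obs, 110)$fraction, 1 / 3)

  set.seed(303)
  g <- function(x) ifelse(x <= 110, exp(-(x - 110)^2 / (2 * 60^2)),
                          exp(-(x - 110)^2 / (2 * 150^2)))
  x <- r_detected_distances(2000, g, 600)
  obs2 <- observation_table(data.frame(
    transect = "t", distance = x, size = 1, det1 = 1, det2 = 0))
  frac <- truncation_fraction(obs2, 110)$fraction
  expected <- mu_closed_form(110, 60, 150, 110) /
    mu_closed_form(110, 60, 150, 600)
  expect_equal(frac, expected, tolerance = 3 * sqrt(expected *
                                                      (1 - expected) / 2000))
})

test_that("the transect bootstrap is deterministic and guards its inputs", {
  set.seed(304)
  scn <- scenario_pooling_baseline()
  sim <- simulate_survey(scn, seed = 305)
  fitter <- function(obs, design)
    fit_cds(obs, design, "half_normal")$abundance$N

  b1 <- bootstrap_variance(fitter, sim$obs, sim$design, B = 60, seed = 9)
  b2 <- bootstrap_variance(fitter, sim$obs, sim$design, B = 60, seed = 9)
  expect_identical(b1$estimates, b2$estimates)
  expect_gt(b1$se, 0)
  expect_lt(b1$ci[1], b1$ci[2])
  # the interval should bracket the point estimate on reasonable data
  N_hat <- fitter(sim$obs, sim$design)
  expect_gt(N_hat, b1$ci[1])
  expect_lt(N_hat, b1$ci[2])

  one <- survey_design(data.frame(transect = "a", length_km = 5),
                       w = 400, area_km2 = 10)
  expect_error(bootstrap_variance(fitter, sim$obs, one, B = 10),
               class = "apexds_single_transect_error")
})

test_that("a failed mark-recapture stage degrades to a partial fit", {
  set.seed(306)
  x <- r_detected_distances(200, function(x) exp(-x^2 / (2 * 80^2)), 400)
  dat <- design_for_distances(x, 400)   # det2 all zero: no duplicates
  expect_warning(
    fit <- fit_mrds(dat$obs, dat$design, "half_normal",
                    independence = "point"),
    "mark-recapture stage failed")
  expect_equal(fit$status, "partial")
  expect_gt(fit$abundance$N, 0)
})

test_that("fit reports carry the standard survey columns", {
  scn <- scenario_recovery()
  sim <- simulate_survey(scn, seed = 307)
  fit <- fit_mrds(sim$obs, sim$design, "two_piece_normal",
                  independence = "point")
  out <- tempfile()
  rep_list <- fit_report(fit, out)
  expect_true(file.exists(paste0(out, ".txt")))
  expect_true(file.exists(paste0(out, ".json")))
  back <- jsonlite::read_json(paste0(out, ".json"))
  for (k in c("N", "se", "theta", "mr_p_mean", "mr_p_min", "mr_p_max",
              "AIC_ds", "ks_D", "left_truncation_pct"))
    expect_true(k %in% names(back))
  expect_equal(back$N, fit$abundance$N, tolerance = 1e-8)
  # apex truncation share sits between the stake fractions seen in practice
  expect_gt(back$left_truncation_pct, 5)
  expect_lt(back$left_truncation_pct, 45)
})
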