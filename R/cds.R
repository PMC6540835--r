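#' Fit a conventional or multiple-covariate distance sampling model
#'
#' Maximizes the conditional likelihood of the observed perpendicular
#' distances, `sum_i log( g(x_i; z_i) / mu(z_i) )`, over the detection
#' parameters. With covariates this is the multiple-covariate (MCDS) model:
#' covariates scale both sigma parameters multiplicatively. Abundance is the
#' Horvitz-Thompson sum computed by [estimate_abundance_cds()] under the
#' assumption of perfect detection at the curve apex.
#'
#' Left truncation at `t` discards detections with `x < t`; for the
#' half-normal the remaining distances are shifted to `x - t` and the
#' effective half-width integrates over `[0, w - t]`. Following the usual
#' aerial-survey practice, `left_truncation = "apex"` truncates at the apex
#' of a two-piece normal fit to the same data, which is where a monotone
#' half-normal becomes defensible.
#'
#' Internally the optimizer works on log(sigma1), log(sigma2) and a logistic
#' transform of theta onto (0, w), so all parameters are unconstrained.
#'
#' @param obs An [observation_table()].
#' @param design A [survey_design()].
#' @param form `"half_normal"` or `"two_piece_normal"`.
#' @param covariates Character vector of covariate columns acting on the
#'   scale (log-linear, shared between the two pieces).
#' @param left_truncation Distance (m) below which detections are dropped,
#'   or `"apex"` (half-normal only). Default 0.
#' @param abundance Compute the abundance block (default `TRUE`).
#' @return A `cds_fit`: fitted [detfn_spec()], log-likelihood, AIC,
#'   variance-covariance of the working parameters, apex estimate, and an
#'   `abundance` element (see [estimate_abundance_cds()]).
#' @export
fit_cds <- function(obs, design, form = c("half_normal", "two_piece_normal"),
                    covariates = character(0), left_truncation = 0,
                    abundance = TRUE) {
  form <- match.arg(form)
  stopifnot(inherits(design, "survey_design"))
  obs <- observation_table(obs, w = design$w)
  w <- design$w

  trunc_t <- left_truncation
  if (identical(left_truncation, "apex")) {
    if (form != "half_normal")
      abort_validation("left_truncation = \"apex\" applies to the half-normal")
    pre <- fit_cds(obs, design, "two_piece_normal", covariates,
                   left_truncation = 0, abundance = FALSE)
    trunc_t <- pre$theta
  }
  if (!is.numeric(trunc_t) || trunc_t < 0 || trunc_t >= w)
    abort_validation("left_truncation must lie in [0, w)")
  if (form == "two_piece_normal" && trunc_t > 0)
    abort_validation("left truncation is only supported for the half-normal")

  keep <- obs$distance >= trunc_t
  obs_kept <- observation_table(as.data.frame(obs)[keep, , drop = FALSE], w = w)
  x_raw <- obs_kept$distance
  x <- x_raw - trunc_t           # working distances, 0-based after truncation
  w_eff <- w - trunc_t
  n <- length(x)
  if (length(unique(x)) < 2)
    abort(paste0("need at least 2 distinct distances after truncation (have ",
                 length(unique(x)), ")"), class = "apexds_insufficient_data")
  if (n < 60)
    warning(sprintf(paste0(
      "only %d detections after truncation; 60-80 are usually needed to ",
      "fit a distance sampling detection model"), n), call. = FALSE)

  Z <- covariate_matrix(obs_kept, covariates)
  xlev <- attr(Z, "xlev")
  p_beta <- ncol(Z)

  make_spec <- function(par) {
    if (form == "half_normal") {
      beta <- par[-1]
      names(beta) <- colnames(Z)
      detfn_spec("half_normal", sigma1 = exp(par[1]), beta = beta,
                 covariate_names = covariates, xlev = xlev, w = w_eff)
    } else {
      beta <- par[-(1:3)]
      names(beta) <- colnames(Z)
      detfn_spec("two_piece_normal",
                 sigma1 = exp(par[2]), sigma2 = exp(par[3]),
                 theta = w_eff * stats::plogis(par[1]), beta = beta,
                 covariate_names = covariates, xlev = xlev, w = w_eff)
    }
  }

  nll <- function(par) {
    spec <- tryCatch(make_spec(par), error = function(e) NULL)
    if (is.null(spec)) return(1e10)
    mult <- if (p_beta) as.numeric(exp(Z %*% par[(length(par) - p_beta + 1):
                                                   length(par)])) else rep(1, n)
    s1 <- spec$sigma1 * mult
    s2 <- spec$sigma2 * mult
    d <- x - spec$theta
    logg <- -d^2 / (2 * ifelse(d <= 0, s1, s2)^2)
    mu <- partial_mu(spec, mult, 0, w_eff)
    val <- -sum(logg - log(mu))
    if (!is.finite(val)) 1e10 else val
  }

  # starting values
  if (form == "half_normal") {
    par0 <- c(log(sqrt(mean(x^2)) + 1e-6), rep(0, p_beta))
  } else {
    dens <- stats::density(x, from = 0, to = w_eff, n = 256)
    th0 <- min(max(dens$x[which.max(dens$y)], 0.05 * w_eff), 0.7 * w_eff)
    lo <- x[x <= th0]; hi <- x[x > th0]
    s1_0 <- if (length(lo) > 4) sqrt(mean((lo - th0)^2)) else th0 / 2 + 1
    s2_0 <- if (length(hi) > 4) sqrt(mean((hi - th0)^2)) else w_eff / 4
    par0 <- c(stats::qlogis(th0 / w_eff), log(s1_0), log(s2_0), rep(0, p_beta))
  }

  if (length(par0) == 1) {
    opt1 <- stats::optimize(function(p) nll(p), interval = log(w_eff) + c(-9, 7))
    opt <- list(par = opt1$minimum, value = opt1$objective, convergence = 0L)
  } else {
    opt <- stats::optim(par0, nll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    opt2 <- tryCatch(
      stats::optim(opt$par, nll, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt2) && opt2$value <= opt$value) opt <- opt2
  }
  if ((opt$convergence %||% 0L) != 0L)
    abort(paste0("detection model did not converge (optim code ",
                 opt$convergence, "; value ", fmt_num(opt$value, 4), ")"),
          class = "apexds_fit_error")

  hess <- tryCatch(stats::optimHess(opt$par, nll), error = function(e) NULL)
  vcov <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e)
      matrix(NA_real_, length(opt$par), length(opt$par)))
  else matrix(NA_real_, length(opt$par), length(opt$par))

  spec <- make_spec(opt$par)
  npar <- length(opt$par)
  loglik <- -opt$value
  theta_hat <- if (form == "two_piece_normal") spec$theta else trunc_t

  fit <- structure(list(
    form = form, spec = spec, par = opt$par, vcov = vcov,
    loglik = loglik, npar = npar, AIC = 2 * npar - 2 * loglik,
    theta = theta_hat, w = w, w_eff = w_eff, left_truncation = trunc_t,
    covariates = covariates, xlev = xlev, n = n,
    obs = obs_kept, design = design,
    likelihood = "ds_conditional",
    convergence = TRUE,
    make_spec = make_spec
  ), class = "cds_fit")

  if (abundance) fit$abundance <- estimate_abundance_cds(fit)
  fit
}

# per-observation effective half-width and apex-relative inclusion prob
fitted_mu <- function(fit, spec = fit$spec) {
  mult <- scale_multiplier(spec, as.data.frame(fit$obs), n = fit$n)
  mu <- partial_mu(spec, mult, 0, fit$w_eff)
  list(mu = mu, Pa = mu / fit$w_eff)
}

#' Horvitz-Thompson abundance from inclusion probabilities
#'
#' The elementary estimator `N = (A / a) * sum(size / Pa)` used by all
#' estimators in the package once each detected group's inclusion
#' probability is known.
#'
#' @param size Group sizes.
#' @param Pa Inclusion probabilities (within the covered strip).
#' @param A Study area (km^2).
#' @param a Covered area (km^2).
#' @return List with `N` (individuals) and `N_groups`.
#' @export
ht_abundance <- function(size, Pa, A, a) {
  if (any(Pa <= 0)) abort_validation("inclusion probabilities must be positive")
  if (any(Pa < 0.01))
    warning("some inclusion probabilities are below 0.01; ",
            "Horvitz-Thompson weights are extreme extrapolations",
            call. = FALSE)
  list(N = (A / a) * sum(size / Pa), N_groups = (A / a) * sum(1 / Pa))
}

#' Abundance under the perfect-apex-detection assumption
#'
#' Horvitz-Thompson abundance from a CDS/MCDS fit: each detected group is
#' weighted by `1 / Pa(z_i)` with `Pa(z) = mu(z) / w`, scaled by study over
#' covered area stratum by stratum. Detection at the apex is assumed
#' certain, which is exactly the assumption the mark-recapture stage of an
#' MRDS model replaces. The standard error combines a delta-method
#' detection-parameter component with the between-transect encounter-rate
#' component of [encounter_rate_variance()]; a transect bootstrap
#' ([bootstrap_variance()]) is the reference alternative.
#'
#' @param fit A `cds_fit`.
#' @param obs,design Override the data stored in the fit (rarely needed).
#' @return List with `N`, `N_groups`, `se`, `se_detection`,
#'   `se_encounter_rate`, `cv`, per-observation `Pa`, and a per-stratum
#'   breakdown.
#' @export
estimate_abundance_cds <- function(fit, obs = NULL, design = NULL) {
  stopifnot(inherits(fit, "cds_fit"))
  obs <- obs %||% fit$obs
  design <- design %||% fit$design
  strat <- obs_stratum(obs, design)
  st <- design$strata
  w_frac <- fit$w_eff / fit$w      # truncation shrinks the covered strip
  Pa <- fitted_mu(fit)$Pa

  N_by <- function(Pa) {
    vapply(seq_len(nrow(st)), function(h) {
      i <- strat == st$stratum[h]
      if (!any(i)) return(0)
      ht_abundance(obs$size[i], Pa[i], st$area_km2[h],
                   st$covered_km2[h] * w_frac)$N
    }, numeric(1))
  }
  N_h <- suppressWarnings(N_by(Pa))
  if (any(Pa < 0.01))
    warning("some inclusion probabilities are below 0.01; ",
            "Horvitz-Thompson weights are extreme extrapolations",
            call. = FALSE)
  N <- sum(N_h)
  N_groups <- sum(vapply(seq_len(nrow(st)), function(h) {
    i <- strat == st$stratum[h]
    if (!any(i)) return(0)
    (st$area_km2[h] / (st$covered_km2[h] * w_frac)) * sum(1 / Pa[i])
  }, numeric(1)))

  # delta method over the working detection parameters
  var_det <- NA_real_
  if (all(is.finite(fit$vcov))) {
    gr <- num_gradient(function(p) {
      spec <- fit$make_spec(p)
      sum(suppressWarnings(N_by(fitted_mu(fit, spec)$Pa)))
    }, fit$par)
    var_det <- max(0, as.numeric(t(gr) %*% fit$vcov %*% gr))
  }

  # encounter-rate component: cv(n)^2 applied stratum by stratum
  var_er <- tryCatch({
    er <- encounter_rate_variance(obs, design)
    sum(vapply(seq_len(nrow(er$by_stratum)), function(h) {
      row <- er$by_stratum[h, ]
      Nh <- N_h[match(row$stratum, st$stratum)]
      if (row$n == 0) 0 else Nh^2 * row$var_n / row$n^2
    }, numeric(1)))
  }, apexds_error = function(e) {
    warning("encounter-rate variance unavailable (",
            conditionMessage(e), "); SE reflects detection only",
            call. = FALSE)
    NA_real_
  })

  total <- sum(c(var_det, var_er), na.rm = TRUE)
  list(N = N, N_groups = N_groups,
       se = sqrt(total),
       se_detection = sqrt(var_det),
       se_encounter_rate = if (is.na(var_er)) NA_real_ else sqrt(var_er),
       cv = sqrt(total) / N,
       Pa = Pa,
       by_stratum = data.frame(stratum = st$stratum, N = N_h))
}

#' Between-transect encounter-rate variance
#'
#' Empirical variance of the encounter rate n/L over replicate transects,
#' `var(n/L) = K / (L^2 (K - 1)) * sum_k l_k^2 (n_k / l_k - n / L)^2`,
#' computed within each stratum and returned both as the rate variance and
#' scaled to `var(n)`. This between-line component typically dominates the
#' variance of line-transect abundance estimates and must be included.
#'
#' @param obs An [observation_table()].
#' @param design A [survey_design()]; transects with no detections count as
#'   zeros.
#' @return List with `var_rate` (var of n/L; `NA` when the design has more
#'   than one stratum), `var_n` (summed over strata), and a per-stratum
#'   table.
#' @export
encounter_rate_variance <- function(obs, design) {
  stopifnot(inherits(design, "survey_design"))
  tr <- design$transects
  counts <- table(factor(obs$transect, levels = tr$transect))
  n_k <- as.numeric(counts)
  by <- lapply(unique(tr$stratum), function(h) {
    i <- tr$stratum == h
    K <- sum(i)
    if (K < 2)
      abort(paste0("stratum \"", h, "\" has a single transect; ",
                   "encounter-rate variance needs replicate lines - ",
                   "use bootstrap_variance()"),
            class = "apexds_single_transect_error")
    l <- tr$length_km[i]
    nk <- n_k[i]
    L <- sum(l)
    n <- sum(nk)
    vr <- K / (L^2 * (K - 1)) * sum(l^2 * (nk / l - n / L)^2)
    data.frame(stratum = h, K = K, L = L, n = n,
               var_rate = vr, var_n = vr * L^2)
  })
  by <- do.call(rbind, by)
  list(var_rate = if (nrow(by) == 1) by$var_rate else NA_real_,
       var_n = sum(by$var_n),
       by_stratum = by)
}

# KS statistic of values against Uniform(0,1), with asymptotic p-value
ks_uniform <- function(u) {
  n <- length(u)
  u <- sort(u)
  D <- max(seq_len(n) / n - u, u - (seq_len(n) - 1) / n)
  lam <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2))
  list(statistic = D, p.value = min(1, max(0, p)))
}

#' Kolmogorov-Smirnov goodness of fit for a distance model
#'
#' Transforms each observed distance by its fitted conditional CDF
#' F(x | z) (a per-observation probability-integral transform, so covariate
#' models are handled naturally) and compares the transformed sample with
#' the uniform distribution.
#'
#' @param fit A `cds_fit`.
#' @param obs Optional observations (defaults to those stored in the fit).
#' @return List with `statistic` (D), `p.value` (asymptotic) and the PIT
#'   values `pit`.
#' @export
gof_ks <- function(fit, obs = NULL) {
  stopifnot(inherits(fit, "cds_fit"))
  obs <- obs %||% fit$obs
  x <- obs$distance - fit$left_truncation
  u <- detection_cdf(fit$spec, x, z = as.data.frame(obs), w = fit$w_eff)
  res <- ks_uniform(u)
  list(statistic = res$statistic, p.value = res$p.value, pit = u)
}

#' Rank fitted models by AIC
#'
#' @param candidates Named list of fits sharing the same observations,
#'   truncation and likelihood type (distance-only likelihoods cannot be
#'   ranked against mark-recapture likelihoods).
#' @return Data frame sorted by AIC (ties within 1e-6 broken in favour of
#'   fewer parameters) with a `dAIC` column; the best model's name is in
#'   `attr(, "best")`.
#' @export
aic_select <- function(candidates) {
  if (is.null(names(candidates)))
    names(candidates) <- paste0("model", seq_along(candidates))
  lik <- vapply(candidates, function(f) f$likelihood %||% NA_character_,
                character(1))
  if (length(unique(lik)) > 1)
    abort(paste0("candidates mix likelihood types (",
                 paste(unique(lik), collapse = ", "),
                 "); their AICs are not comparable"),
          class = "apexds_comparability_error")
  ns <- vapply(candidates, function(f) f$n, numeric(1))
  tr <- vapply(candidates, function(f) f$left_truncation %||% 0, numeric(1))
  if (length(unique(ns)) > 1 || length(unique(tr)) > 1)
    abort("candidates were fitted to different data or truncation",
          class = "apexds_comparability_error")
  df <- data.frame(
    model = names(candidates),
    npar = vapply(candidates, function(f) f$npar, numeric(1)),
    loglik = vapply(candidates, function(f) f$loglik, numeric(1)),
    AIC = vapply(candidates, function(f) f$AIC, numeric(1)),
    row.names = NULL
  )
  ord <- order(df$AIC, df$npar)
  # ties within 1e-6 resolve in favour of the simpler model
  for (i in seq_len(length(ord) - 1)) {
    a <- ord[i]; b <- ord[i + 1]
    if (abs(df$AIC[a] - df$AIC[b]) < 1e-6 && df$npar[b] < df$npar[a]) {
      ord[i] <- b; ord[i + 1] <- a
    }
  }
  df <- df[ord, ]
  df$dAIC <- df$AIC - df$AIC[1]
  attr(df, "best") <- df$model[1]
  df
}

#' @export
print.cds_fit <- function(x, ...) {
  cat(sprintf("%s distance sampling fit (n = %d, w = %.0f m",
              if (length(x$covariates)) "Multiple-covariate" else "Conventional",
              x$n, x$w))
  if (x$left_truncation > 0)
    cat(sprintf(", left-truncated at %.1f m", x$left_truncation))
  cat(")\n")
  print(x$spec)
  cat(sprintf("  logLik = %.3f, k = %d, AIC = %.3f\n",
              x$loglik, x$npar, x$AIC))
  if (!is.null(x$abundance))
    cat(sprintf("  N = %.1f (SE %.1f)\n", x$abundance$N, x$abundance$se))
  invisible(x)
}
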