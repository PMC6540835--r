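#' Fit a mark-recapture distance sampling (MRDS) model
#'
#' Two-stage estimator combining a distance sampling detection shape with a
#' double-observer mark-recapture scale:
#'
#' 1. the MCDS conditional distance likelihood is maximized on the pooled
#'    detections (detected by at least one observer), giving an initial
#'    apex estimate;
#' 2. the conditional mark-recapture model of [fit_mr_conditional()] is
#'    fitted (by default with a log link and the apex-centered distance
#'    basis, the specification that can represent multiplicative
#'    apex-peaked detection);
#' 3. under *point independence* the distance stage is then refitted
#'    through the pooled-curve likelihood: the single-observer detection
#'    curve is `q_j(z) * g(x; z)` with shape `g` from the distance family
#'    and apex scale `q_j(z)` plugged in from the mark-recapture stage, so
#'    the pooled detections follow `p.(x, z) = 1 - (1 - q1 g)(1 - q2 g)`.
#'    Fitting the 2PN to this pooled curve (rather than pretending the
#'    pooled curve is itself 2PN) removes an asymptotic bias of several
#'    percent in both the apex and the effective strip width. Stages 2-3
#'    alternate twice so the mark-recapture basis is centered on the final
#'    apex.
#'
#' Point-independence inclusion probabilities are
#' `Pa(z) = (1/w) int_0^w p.(x, z) dx` with the mark-recapture model used
#' *only* through its apex value `q_j(z)`; full independence instead trusts
#' the mark-recapture model at every distance,
#' `Pa(z) = (1/w) int_0^w [1 - (1 - p1(x,z))(1 - p2(x,z))] dx`. Abundance
#' is the Horvitz-Thompson sum of `size / Pa` scaled by study over covered
#' area, stratum by stratum.
#'
#' The stages are kept separate (rather than jointly maximized) so that a
#' stage failure remains diagnosable; when the mark-recapture stage fails
#' the distance-only result is returned with `status = "partial"`.
#'
#' @param obs An [observation_table()] (pooled over observers).
#' @param design A [survey_design()].
#' @param form Detection form for the distance stage.
#' @param ds_covariates,mr_covariates Covariates for the two stages.
#' @param independence `"point"` (default) or `"full"`.
#' @param left_truncation Passed to the distance stage.
#' @param mr_distance,mr_link,observer_effect Passed to the MR stage
#'   (defaults: apex-centered piecewise-quadratic basis, log link).
#' @return An `mrds_fit` with elements `ds` (the stage-1 MCDS fit, whose
#'   AIC is the distance-component AIC comparable with CDS fits), `mr`,
#'   `shape` (the pooled-curve refit, point mode), `theta`, `Pa`,
#'   `abundance` (N, SE and components), `mr_p` (mean/min/max apex
#'   probability), and `status`.
#' @export
fit_mrds <- function(obs, design, form = c("two_piece_normal", "half_normal"),
                     ds_covariates = character(0),
                     mr_covariates = character(0),
                     independence = c("point", "full"),
                     left_truncation = 0,
                     mr_distance = "apex_quadratic", mr_link = "log",
                     observer_effect = FALSE) {
  form <- match.arg(form)
  independence <- match.arg(independence)

  ds <- fit_cds(obs, design, form = form, covariates = ds_covariates,
                left_truncation = left_truncation, abundance = FALSE)
  theta <- ds$theta
  th_work <- if (form == "two_piece_normal") theta else 0  # working scale
  obs_kept <- ds$obs
  z <- as.data.frame(obs_kept)

  fit_mr_stage <- function(th) {
    fit_mr_conditional(obs_kept, covariates = mr_covariates,
                       mode = independence, distance = mr_distance,
                       link = mr_link, observer_effect = observer_effect,
                       theta = th)
  }
  mr <- tryCatch(fit_mr_stage(th_work), error = function(e) e)
  if (inherits(mr, "error")) {
    warning("mark-recapture stage failed (", conditionMessage(mr),
            "); returning the distance-only fit", call. = FALSE)
    ds$abundance <- estimate_abundance_cds(ds)
    return(structure(list(ds = ds, mr = NULL, independence = independence,
                          theta = theta, status = "partial",
                          abundance = ds$abundance,
                          n = ds$n, likelihood = "mrds"),
                     class = "mrds_fit"))
  }

  shape <- NULL
  if (independence == "point") {
    # alternate MR scale and pooled-curve shape so the MR basis is
    # centered on the final apex estimate
    for (round in 1:2) {
      q <- mr_apex_q(mr, z)
      shape <- fit_pooled_shape(ds, q)
      th_new <- if (form == "two_piece_normal") shape$spec$theta else 0
      if (round == 1 && abs(th_new - (mr$theta %||% 0)) > 1e-6)
        mr <- fit_mr_stage(th_new)
    }
    theta <- if (form == "two_piece_normal") shape$spec$theta
    else ds$left_truncation
    th_work <- if (form == "two_piece_normal") shape$spec$theta else 0
  }
  boundary_theta <- form == "two_piece_normal" &&
    (th_work < 0.02 * ds$w_eff || th_work > 0.98 * ds$w_eff)
  if (boundary_theta)
    warning(sprintf("apex estimate %.1f m is at the boundary of (0, w)",
                    th_work), call. = FALSE)

  gl <- gauss_legendre(41, 0, ds$w_eff)

  Pa_of <- function(shape_par, mr_coefs) {
    m <- mr
    m$coefficients <- mr_coefs
    if (independence == "point") {
      spec <- shape$make_spec(shape_par)
      q <- mr_apex_q(m, z)
      pooled_mu(spec, z, q, gl) / ds$w_eff
    } else if (length(mr_covariates) == 0) {
      rep(sum(gl$weights * pooled_probability(m, gl$nodes)) / ds$w_eff, ds$n)
    } else {
      pp <- vapply(seq_len(ds$n), function(i) {
        sum(gl$weights * pooled_probability(m, gl$nodes, z[i, , drop = FALSE]))
      }, numeric(1))
      pp / ds$w_eff
    }
  }

  Pa <- Pa_of(if (independence == "point") shape$par else NULL,
              mr$coefficients)
  strat <- obs_stratum(obs_kept, design)
  st <- design$strata
  w_frac <- ds$w_eff / ds$w

  N_by <- function(Pa) {
    vapply(seq_len(nrow(st)), function(h) {
      i <- strat == st$stratum[h]
      if (!any(i)) return(0)
      suppressWarnings(
        ht_abundance(obs_kept$size[i], Pa[i], st$area_km2[h],
                     st$covered_km2[h] * w_frac)$N)
    }, numeric(1))
  }
  N_h <- N_by(Pa)
  N <- sum(N_h)
  N_groups <- sum(vapply(seq_len(nrow(st)), function(h) {
    i <- strat == st$stratum[h]
    if (!any(i)) return(0)
    (st$area_km2[h] / (st$covered_km2[h] * w_frac)) * sum(1 / Pa[i])
  }, numeric(1)))

  # delta method over both stages' parameters (block-diagonal covariance:
  # the two conditional likelihoods share no parameters, and theta-hat is
  # treated as fixed - apex uncertainty is picked up by the bootstrap)
  var_det <- NA_real_
  shape_par <- if (independence == "point") shape$par else numeric(0)
  shape_vcov <- if (independence == "point") shape$vcov else
    matrix(numeric(0), 0, 0)
  if (all(is.finite(shape_vcov)) && all(is.finite(mr$vcov))) {
    k_ds <- length(shape_par)
    gr <- num_gradient(function(p) {
      sum(N_by(Pa_of(p[seq_len(k_ds)], p[k_ds + seq_len(mr$npar)])))
    }, c(shape_par, mr$coefficients))
    V <- matrix(0, k_ds + mr$npar, k_ds + mr$npar)
    if (k_ds) V[seq_len(k_ds), seq_len(k_ds)] <- shape_vcov
    V[k_ds + seq_len(mr$npar), k_ds + seq_len(mr$npar)] <- mr$vcov
    var_det <- max(0, as.numeric(t(gr) %*% V %*% gr))
  }
  var_er <- tryCatch({
    er <- encounter_rate_variance(obs_kept, design)
    sum(vapply(seq_len(nrow(er$by_stratum)), function(h) {
      row <- er$by_stratum[h, ]
      Nh <- N_h[match(row$stratum, st$stratum)]
      if (row$n == 0) 0 else Nh^2 * row$var_n / row$n^2
    }, numeric(1)))
  }, apexds_error = function(e) NA_real_)
  total <- sum(c(var_det, var_er), na.rm = TRUE)

  mr_p <- if (mr$boundary) {
    list(mean = 1, se = 0, min = 1, max = 1)
  } else {
    mean_apex_probability(mr, obs_kept, theta = th_work, weights = "ht",
                          Pa = Pa)
  }

  structure(list(
    ds = ds, mr = mr, shape = shape, independence = independence,
    theta = theta, boundary_theta = boundary_theta,
    Pa = Pa, status = "ok",
    abundance = list(N = N, N_groups = N_groups, se = sqrt(total),
                     se_detection = sqrt(var_det),
                     se_encounter_rate =
                       if (is.na(var_er)) NA_real_ else sqrt(var_er),
                     cv = sqrt(total) / N,
                     by_stratum = data.frame(stratum = st$stratum, N = N_h)),
    mr_p = mr_p,
    AIC = ds$AIC + mr$AIC,
    n = ds$n, likelihood = "mrds"
  ), class = "mrds_fit")
}

# per-observation apex detection probabilities (q1, q2) from the MR stage
mr_apex_q <- function(mr, z) {
  th <- mr$theta %||% 0
  p <- mr_probabilities(mr, rep(th, nrow(z)), z)
  list(q1 = p$p1, q2 = p$p2)
}

# int_0^w [1 - (1 - q1 g)(1 - q2 g)] dx per observation, on GL nodes
pooled_mu <- function(spec, z, q, gl) {
  mult <- scale_multiplier(spec, z, n = length(q$q1))
  s1 <- spec$sigma1 * mult
  s2 <- spec$sigma2 * mult
  th <- spec$theta
  acc <- numeric(length(mult))
  for (j in seq_along(gl$nodes)) {
    d <- gl$nodes[j] - th
    g <- exp(-d^2 / (2 * (if (d <= 0) s1 else s2)^2))
    acc <- acc + gl$weights[j] * (1 - (1 - q$q1 * g) * (1 - q$q2 * g))
  }
  acc
}

# refit the single-observer detection shape through the pooled-curve
# likelihood, with apex scales q fixed from the mark-recapture stage
fit_pooled_shape <- function(ds, q) {
  x <- ds$obs$distance - ds$left_truncation
  z <- as.data.frame(ds$obs)
  gl <- gauss_legendre(41, 0, ds$w_eff)
  nll <- function(par) {
    spec <- tryCatch(ds$make_spec(par), error = function(e) NULL)
    if (is.null(spec)) return(1e10)
    mult <- scale_multiplier(spec, z, n = length(x))
    s1 <- spec$sigma1 * mult
    s2 <- spec$sigma2 * mult
    d <- x - spec$theta
    g <- exp(-d^2 / (2 * ifelse(d <= 0, s1, s2)^2))
    p_obs <- 1 - (1 - q$q1 * g) * (1 - q$q2 * g)
    mu <- pooled_mu(spec, z, q, gl)
    val <- -sum(log(p_obs) - log(mu))
    if (!is.finite(val)) 1e10 else val
  }
  opt <- stats::optim(ds$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt2 <- tryCatch(
    stats::optim(opt$par, nll, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(opt2) && opt2$value <= opt$value) opt <- opt2
  hess <- tryCatch(stats::optimHess(opt$par, nll), error = function(e) NULL)
  vcov <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e)
      matrix(NA_real_, length(opt$par), length(opt$par)))
  else matrix(NA_real_, length(opt$par), length(opt$par))
  list(par = opt$par, vcov = vcov, spec = ds$make_spec(opt$par),
       loglik = -opt$value, make_spec = ds$make_spec)
}

#' @export
print.mrds_fit <- function(x, ...) {
  cat(sprintf("MRDS fit (%s independence, %s detection, n = %d)\n",
              x$independence, x$ds$form, x$n))
  if (x$status != "ok") cat("  ** partial fit: distance stage only **\n")
  cat(sprintf("  apex theta = %.1f m\n", x$theta))
  if (!is.null(x$mr_p))
    cat(sprintf("  mean apex MR p = %.3f (SE %.3f), range [%.3f, %.3f]\n",
                x$mr_p$mean, x$mr_p$se, x$mr_p$min, x$mr_p$max))
  cat(sprintf("  N = %.1f (SE %.1f)\n", x$abundance$N, x$abundance$se))
  invisible(x)
}

#' Transect bootstrap for abundance variance
#'
#' Resamples transects with replacement (within strata, preserving each
#' stratum's number of lines), rebuilds the observation table, refits the
#' full estimator, and summarizes the replicate abundances. Encounter-rate
#' variance is captured by construction, and the apex estimate is
#' re-estimated on every replicate, so its uncertainty propagates too.
#'
#' @param fitter Function of `(obs, design)` returning either a number or a
#'   fit with an `abundance$N` element.
#' @param obs An [observation_table()].
#' @param design A [survey_design()] with at least 2 transects.
#' @param B Number of bootstrap replicates (at least 100 recommended).
#' @param seed RNG seed; identical inputs and seed give identical results.
#' @return List with `se`, percentile `ci` (2.5 and 97.5 percent), the
#'   replicate `estimates`, and the number of failed replicates `n_fail`
#'   (failures beyond 20 percent abort).
#' @export
bootstrap_variance <- function(fitter, obs, design, B = 200, seed = 1L) {
  stopifnot(inherits(design, "survey_design"))
  if (nrow(design$transects) < 2)
    abort("bootstrap requires at least 2 transects",
          class = "apexds_single_transect_error")
  obs <- as.data.frame(obs)
  tr <- design$transects
  area_by <- stats::setNames(design$strata$area_km2, design$strata$stratum)
  ests <- with_seed(seed, vapply(seq_len(B), function(b) {
    pick <- unlist(lapply(unique(tr$stratum), function(h) {
      idx <- which(tr$stratum == h)
      sample(idx, length(idx), replace = TRUE)
    }))
    tr_b <- tr[pick, , drop = FALSE]
    tr_b$transect <- paste0(tr_b$transect, ".", seq_along(pick))
    rows <- lapply(seq_along(pick), function(j) {
      o <- obs[obs$transect == tr$transect[pick[j]], , drop = FALSE]
      if (nrow(o)) o$transect <- tr_b$transect[j]
      o
    })
    obs_b <- do.call(rbind, rows)
    des_b <- survey_design(tr_b, w = design$w, area_km2 = area_by,
                           sides = design$sides)
    out <- tryCatch(suppressWarnings(fitter(obs_b, des_b)),
                    error = function(e) NULL)
    if (is.null(out)) return(NA_real_)
    if (is.numeric(out)) out[1] else out$abundance$N
  }, numeric(1)))
  n_fail <- sum(!is.finite(ests))
  if (n_fail > 0.2 * B)
    abort(sprintf("%d of %d bootstrap replicates failed to fit", n_fail, B),
          class = "apexds_fit_error")
  ok <- ests[is.finite(ests)]
  list(se = stats::sd(ok),
       ci = stats::quantile(ok, c(0.025, 0.975), names = FALSE),
       estimates = ests, B = B, n_fail = n_fail)
}

#' Left-truncation fraction at a candidate apex
#'
#' Share of detections closer to the line than `theta` - the data a
#' half-normal analysis would discard if it truncated at the apex of the
#' detection curve.
#'
#' @param obs An [observation_table()].
#' @param theta Apex distance (m).
#' @return List with `count`, `fraction` and `percent`.
#' @export
truncation_fraction <- function(obs, theta) {
  obs <- observation_table(obs)
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0)
    abort_validation("theta must be a single non-negative distance")
  cnt <- sum(obs$distance < theta)
  frac <- if (nrow(obs)) cnt / nrow(obs) else 0
  list(count = cnt, fraction = frac, percent = 100 * frac)
}

#' Plain-text and machine-readable fit report
#'
#' Writes the standard survey-report column set: abundance with SE and
#' normal CI, apex distance, mean/min/max apex mark-recapture probability,
#' AIC, Kolmogorov-Smirnov goodness of fit, and the apex left-truncation
#' fraction.
#'
#' @param fit A `cds_fit` or `mrds_fit`.
#' @param file Optional path; with `file = "report"` both `report.txt` and
#'   `report.json` are written.
#' @return The report as a named list, invisibly if written to file.
#' @export
fit_report <- function(fit, file = NULL) {
  if (inherits(fit, "mrds_fit")) {
    ds <- fit$ds
    ab <- fit$abundance
    rep_list <- list(
      model = paste0("mrds_", substr(fit$independence, 1, 1), "i_",
                     if (ds$form == "two_piece_normal") "2pn" else "hn"),
      n = fit$n, N = ab$N, N_groups = ab$N_groups, se = ab$se,
      ci_lower = ab$N - 1.96 * ab$se, ci_upper = ab$N + 1.96 * ab$se,
      theta = fit$theta,
      mr_p_mean = fit$mr_p$mean, mr_p_se = fit$mr_p$se,
      mr_p_min = fit$mr_p$min, mr_p_max = fit$mr_p$max,
      AIC_ds = ds$AIC, AIC_mr = if (is.null(fit$mr)) NA else fit$mr$AIC,
      AIC = fit$AIC
    )
  } else {
    stopifnot(inherits(fit, "cds_fit"))
    ds <- fit
    ab <- fit$abundance %||% estimate_abundance_cds(fit)
    rep_list <- list(
      model = paste0("cds_",
                     if (ds$form == "two_piece_normal") "2pn" else "hn"),
      n = fit$n, N = ab$N, N_groups = ab$N_groups, se = ab$se,
      ci_lower = ab$N - 1.96 * ab$se, ci_upper = ab$N + 1.96 * ab$se,
      theta = fit$theta, AIC = fit$AIC
    )
  }
  ks <- tryCatch(gof_ks(ds), error = function(e) NULL)
  if (!is.null(ks)) {
    rep_list$ks_D <- ks$statistic
    rep_list$ks_p <- ks$p.value
  }
  tf <- truncation_fraction(ds$obs, if (ds$form == "two_piece_normal")
    fit$theta else ds$left_truncation)
  rep_list$left_truncation_pct <- tf$percent

  if (!is.null(file)) {
    lines <- c("apexds fit report",
               strrep("-", 40),
               vapply(names(rep_list), function(k) {
                 v <- rep_list[[k]]
                 sprintf("%-22s %s", k,
                         if (is.numeric(v)) fmt_num(v, 4) else as.character(v))
               }, character(1)))
    writeLines(lines, paste0(file, ".txt"))
    jsonlite::write_json(rep_list, paste0(file, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(rep_list))
  }
  rep_list
}
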