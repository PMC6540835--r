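#' Fit a double-observer mark-recapture detection model
#'
#' Conditional (on detection by at least one observer) likelihood for the
#' capture histories of detected groups. Each observer's detection is
#' modeled through a link function of a linear predictor in distance and
#' covariates, and the three observable histories (1,0), (0,1), (1,1) have
#' probabilities normalized by `1 - P(0,0)` under independence between
#' observers.
#'
#' Distance can enter three ways:
#' * `"linear"` (default): `a0 + a_x x`, the classical monotone form;
#' * `"quadratic"`: adds `x^2`;
#' * `"apex_quadratic"`: piecewise linear-plus-quadratic in `d = x - theta`
#'   with separate coefficients on either side of the apex. At `x = theta`
#'   the predictor reduces to the intercept (plus covariates), so the apex
#'   detection probability is parameterized directly. This is the basis
#'   that can actually represent detection that rises to an apex and falls
#'   asymmetrically; it requires `theta`.
#'
#' The `link` is `"logit"` (classical double-observer logistic regression)
#' or `"log"`, under which detection factorizes multiplicatively as
#' (apex detectability) x (distance decay) - the natural structure of
#' aerial survey detection and the one [fit_mrds()] uses.
#'
#' Under *full* independence the fitted pooled probability is trusted at
#' every distance; under *point* independence it is only ever evaluated at
#' the apex, where detection is near its maximum and un-modeled
#' heterogeneity does the least damage.
#'
#' @param obs An [observation_table()] with `det1`/`det2` capture histories.
#' @param covariates Covariate columns entering both observers' predictors.
#' @param mode `"point"` or `"full"` independence.
#' @param distance `"linear"`, `"quadratic"` or `"apex_quadratic"`.
#' @param link `"logit"` or `"log"`.
#' @param observer_effect Add a role indicator for observer 2 (pilot versus
#'   back-seat asymmetry). Default `FALSE` (symmetric observers).
#' @param theta Apex distance; required for `"apex_quadratic"` and for
#'   point-independence evaluation (may be set by [fit_mrds()]).
#' @return An `mr_fit` with coefficients, covariance, log-likelihood and
#'   AIC. Degenerate data (no discordant histories) yield a boundary fit
#'   with `boundary = TRUE` and detection probabilities pinned at 1.
#' @export
fit_mr_conditional <- function(obs, covariates = character(0),
                               mode = c("point", "full"),
                               distance = c("linear", "quadratic",
                                            "apex_quadratic"),
                               link = c("logit", "log"),
                               observer_effect = FALSE,
                               theta = NULL) {
  mode <- match.arg(mode)
  distance <- match.arg(distance)
  link <- match.arg(link)
  obs <- observation_table(obs)
  if (distance == "apex_quadratic" && is.null(theta))
    abort_validation("apex_quadratic distance basis requires theta")
  d1 <- obs$det1
  d2 <- obs$det2
  n <- nrow(obs)
  if (sum(d1 & d2) < 1)
    abort(paste0("no duplicate (1,1) capture histories: conditional ",
                 "detection probabilities are inestimable"),
          class = "apexds_boundary_error")
  Z <- covariate_matrix(obs, covariates)
  xlev <- attr(Z, "xlev")
  X <- mr_basis(obs$distance, distance, theta)
  if (ncol(Z)) X <- cbind(X, Z)
  # drop structurally constant basis columns (e.g. near-side terms when the
  # apex sits on the line), keeping the intercept
  keep_cols <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                             function(col) stats::sd(col) > 0))
  X <- X[, keep_cols, drop = FALSE]

  boundary <- sum(d1 + d2 == 1) == 0
  if (boundary) {
    warning("all histories are duplicates; conditional detection ",
            "probabilities lie on the p = 1 boundary", call. = FALSE)
    coefs <- stats::setNames(
      c(if (link == "logit") 20 else -1e-9,
        rep(0, ncol(X) - 1 + observer_effect)),
      c(colnames(X), if (observer_effect) "observer2"))
    return(structure(list(
      coefficients = coefs,
      vcov = matrix(NA_real_, length(coefs), length(coefs)),
      loglik = 0, npar = length(coefs), AIC = NA_real_,
      mode = mode, distance = distance, link = link, theta = theta,
      boundary = TRUE, penalized = FALSE,
      covariates = covariates, xlev = xlev, basis_cols = colnames(X),
      observer_effect = observer_effect,
      n = n, likelihood = "mr_conditional", obs = obs
    ), class = "mr_fit"))
  }

  linkinv <- mr_linkinv(link)
  p_par <- ncol(X) + as.integer(observer_effect)
  nll <- function(a, ridge = 0) {
    eta <- as.numeric(X %*% a[seq_len(ncol(X))])
    off2 <- if (observer_effect) a[p_par] else 0
    p1 <- linkinv(eta)
    p2 <- linkinv(eta + off2)
    ll <- d1 * log(p1) + (1 - d1) * log1p(-p1) +
      d2 * log(p2) + (1 - d2) * log1p(-p2) -
      log1p(-(1 - p1) * (1 - p2))
    val <- -sum(ll) + ridge * sum(a^2)
    if (!is.finite(val)) 1e10 else val
  }

  fit_once <- function(ridge) {
    a0 <- rep(0, p_par)
    if (link == "log") a0[1] <- -0.5      # start inside the p < 1 region
    opt <- stats::optim(a0, nll, ridge = ridge, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (p_par > 1) {
      opt2 <- stats::optim(opt$par, nll, ridge = ridge,
                           method = "Nelder-Mead",
                           control = list(maxit = 3000, reltol = 1e-12))
      if (opt2$value < opt$value) opt <- opt2
    }
    opt
  }

  opt <- fit_once(0)
  penalized <- FALSE
  if (max(abs(opt$par)) > 25) {       # separation guard
    warning("mark-recapture coefficients diverged (possible complete ",
            "separation); refitting with a small ridge penalty",
            call. = FALSE)
    opt <- fit_once(0.01)
    penalized <- TRUE
  }
  hess <- tryCatch(stats::optimHess(opt$par, nll, ridge = 0.01 * penalized),
                   error = function(e) NULL)
  vcov <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e)
      matrix(NA_real_, p_par, p_par))
  else matrix(NA_real_, p_par, p_par)

  coefs <- stats::setNames(opt$par,
                           c(colnames(X), if (observer_effect) "observer2"))
  loglik <- -nll(opt$par)
  structure(list(
    coefficients = coefs, vcov = vcov, loglik = loglik, npar = p_par,
    AIC = 2 * p_par - 2 * loglik, mode = mode, distance = distance,
    link = link, theta = theta,
    boundary = FALSE, penalized = penalized,
    covariates = covariates, xlev = xlev, basis_cols = colnames(X),
    observer_effect = observer_effect,
    n = n, likelihood = "mr_conditional", obs = obs
  ), class = "mr_fit")
}

mr_linkinv <- function(link) {
  if (link == "logit") stats::plogis
  else function(eta) exp(pmin(eta, -1e-9))   # log link, p capped below 1
}

# distance basis for the MR linear predictor
mr_basis <- function(x, distance, theta) {
  X <- cbind(`(Intercept)` = rep(1, length(x)))
  if (distance == "linear") {
    X <- cbind(X, distance = x)
  } else if (distance == "quadratic") {
    X <- cbind(X, distance = x, distance2 = x^2)
  } else {                                   # apex_quadratic
    d <- x - theta
    near <- d <= 0
    X <- cbind(X,
               d_near = ifelse(near, d, 0),
               d_far = ifelse(near, 0, d),
               d2_near = ifelse(near, d^2, 0),
               d2_far = ifelse(near, 0, d^2))
  }
  X
}

# per-observer detection probabilities at distance x and covariates z
mr_linear_predictor <- function(mr, x, z = NULL) {
  n <- length(x)
  Z <- if (length(mr$covariates)) {
    if (is.null(z)) abort_validation("mr model has covariates; z required")
    covariate_matrix(as.data.frame(z), mr$covariates, mr$xlev)
  } else matrix(numeric(0), n, 0)
  X <- mr_basis(x, mr$distance, mr$theta)
  if (ncol(Z)) {
    if (nrow(Z) == 1 && n > 1) Z <- Z[rep(1, n), , drop = FALSE]
    X <- cbind(X, Z)
  }
  X <- X[, mr$basis_cols, drop = FALSE]      # columns kept at fit time
  k <- ncol(X)
  eta <- as.numeric(X %*% mr$coefficients[seq_len(k)])
  list(eta1 = eta,
       eta2 = eta + if (mr$observer_effect) mr$coefficients[k + 1] else 0)
}

mr_probabilities <- function(mr, x, z = NULL) {
  lp <- mr_linear_predictor(mr, x, z)
  inv <- mr_linkinv(mr$link)
  list(p1 = inv(lp$eta1), p2 = inv(lp$eta2))
}

#' Pooled detection probability from a mark-recapture model
#'
#' `pooled_probability()` returns `p1 + p2 - p1 p2` (detection by at least
#' one observer) at arbitrary distances; `apex_probability()` evaluates it
#' at the apex distance, which is the only place a point-independence model
#' is trusted.
#'
#' @param mr An `mr_fit`.
#' @param x Distances (m).
#' @param theta Apex distance (m); defaults to the value stored in the fit.
#' @param z Optional covariate data frame (one row or one per distance).
#' @return Pooled detection probabilities.
#' @export
pooled_probability <- function(mr, x, z = NULL) {
  p <- mr_probabilities(mr, x, z)
  unname(p$p1 + p$p2 - p$p1 * p$p2)
}

#' @rdname pooled_probability
#' @export
apex_probability <- function(mr, theta = mr$theta, z = NULL) {
  if (is.null(theta))
    abort_validation("no apex distance available; supply theta")
  n <- if (is.null(z)) 1L else nrow(as.data.frame(z))
  pooled_probability(mr, rep(theta, n), z)
}

#' Mean apex mark-recapture probability over detections
#'
#' Weighted mean of the per-detection pooled probabilities at the apex,
#' the quantity usually reported as the survey-level mark-recapture
#' correction. Default weights are Horvitz-Thompson (1/Pa, so the mean
#' refers to the population rather than the detected sample); equal weights
#' are also available. The standard error propagates the coefficient
#' covariance by the delta method; the range of individual probabilities is
#' reported alongside.
#'
#' @param mr An `mr_fit`.
#' @param obs Observations whose covariates define the averaging set;
#'   defaults to those stored in the fit.
#' @param theta Apex distance (m).
#' @param weights `"ht"` (default) or `"equal"`.
#' @param Pa Per-observation inclusion probabilities, required for
#'   `weights = "ht"` (supplied automatically by [fit_mrds()]).
#' @return List with `mean`, `se`, `min`, `max`.
#' @export
mean_apex_probability <- function(mr, obs = NULL, theta = mr$theta,
                                  weights = c("ht", "equal"), Pa = NULL) {
  weights <- match.arg(weights)
  obs <- obs %||% mr$obs
  if (is.null(theta))
    abort_validation("no apex distance available; supply theta")
  wts <- if (weights == "ht") {
    if (is.null(Pa))
      abort_validation("weights = \"ht\" needs inclusion probabilities Pa")
    1 / Pa
  } else rep(1, nrow(obs))
  p_of <- function(coefs) {
    m <- mr
    m$coefficients <- coefs
    apex_probability(m, theta, z = as.data.frame(obs))
  }
  p_i <- p_of(mr$coefficients)
  mean_p <- sum(wts * p_i) / sum(wts)
  se <- NA_real_
  if (all(is.finite(mr$vcov))) {
    gr <- num_gradient(function(a) {
      pv <- p_of(a)
      sum(wts * pv) / sum(wts)
    }, mr$coefficients)
    se <- sqrt(max(0, as.numeric(t(gr) %*% mr$vcov %*% gr)))
  }
  list(mean = mean_p, se = se, min = min(p_i), max = max(p_i))
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf(
    "Double-observer mark-recapture fit (%s independence, %s link, n = %d)\n",
    x$mode, x$link, x$n))
  if (x$boundary) cat("  boundary fit: all histories duplicates, p -> 1\n")
  cat("  coefficients:\n")
  print(round(x$coefficients, 5))
  if (!x$boundary)
    cat(sprintf("  logLik = %.3f, k = %d, AIC = %.3f\n",
                x$loglik, x$npar, x$AIC))
  invisible(x)
}
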