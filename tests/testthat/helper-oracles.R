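# independent oracles and small fixture builders used across the suite

# Gauss-Hermite nodes/weights (Golub-Welsch), for E[f(eps)], eps ~ N(0, tau^2)
gh_rule <- function(n = 41) {
  i <- seq_len(n - 1)
  a <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- a
  J[cbind(i + 1, i)] <- a
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = e$vectors[1, ]^2 * sqrt(pi))
}

gh_expect <- function(f, tau, rule = gh_rule()) {
  sum(rule$w / sqrt(pi) * f(sqrt(2) * tau * rule$x))
}

# rejection sampler for distances under an arbitrary detection curve on [0, w]
r_detected_distances <- function(n, gfun, w) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- runif(4 * n, 0, w)
    out <- c(out, x[runif(length(x)) < gfun(x)])
  }
  out[seq_len(n)]
}

# two-transect design with A = a (census geometry) for fixed distances
design_for_distances <- function(x, w, L_km = 10, area = NULL) {
  tr <- data.frame(transect = c("t1", "t2"), length_km = L_km / 2,
                   stratum = "all", stringsAsFactors = FALSE)
  a <- (w / 1000) * L_km
  design <- survey_design(tr, w = w, area_km2 = area %||% a, sides = 1)
  obs <- observation_table(data.frame(
    transect = rep(c("t1", "t2"), length.out = length(x)),
    distance = x, size = 1, det1 = 1, det2 = 0,
    stringsAsFactors = FALSE), w = w)
  list(obs = obs, design = design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# closed-form two-piece-normal effective half-width (independent of package)
mu_closed_form <- function(theta, s1, s2, w) {
  s1 * sqrt(2 * pi) * (pnorm(theta / s1) - 0.5) +
    s2 * sqrt(2 * pi) * (pnorm((w - theta) / s2) - 0.5)
}
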