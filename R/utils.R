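# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(msg, class = "apexds_error") {
  stop(structure(
    class = c(class, "apexds_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

abort_validation <- function(msg) abort(msg, class = "apexds_validation_error")

# run expr with a private RNG stream; the caller's .Random.seed is untouched
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# derive a replicate-level seed below 2^31 from a base seed
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch)
gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1)
  off <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (b - a) / 2 * x[ord] + (a + b) / 2, weights = (b - a) / 2 * w[ord])
}

# central-difference gradient, steps scaled to parameter magnitude
num_gradient <- function(f, par, eps = 1e-5) {
  vapply(seq_along(par), function(j) {
    h <- eps * (1 + abs(par[j]))
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
}

# zero-truncated Poisson sampler (group sizes are >= 1)
rztpois <- function(n, lambda) {
  if (lambda <= 0) return(rep(1L, n))
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

# design matrix for covariates: treatment dummy coding, intercept dropped.
# xlev pins factor levels so prediction matches the fit.
covariate_matrix <- function(data, covariates, xlev = NULL) {
  n <- nrow(data)
  if (length(covariates) == 0)
    return(structure(matrix(numeric(0), n, 0), xlev = list()))
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    abort_validation(paste0("covariates not found in observations: ",
                            paste(miss, collapse = ", ")))
  z <- as.data.frame(data)[covariates]
  for (nm in names(z)) {
    if (is.character(z[[nm]]) || is.logical(z[[nm]])) z[[nm]] <- factor(z[[nm]])
    if (is.factor(z[[nm]]) && !is.null(xlev[[nm]]))
      z[[nm]] <- factor(as.character(z[[nm]]), levels = xlev[[nm]])
  }
  lev <- lapply(Filter(is.factor, z), levels)
  mm <- stats::model.matrix(~ ., data = z)
  structure(mm[, -1, drop = FALSE], xlev = lev)
}

fmt_num <- function(x, digits = 2) formatC(x, format = "f", digits = digits)
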