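# Shared helpers: independent brute-force oracles and small fixtures.

# 1-D brute-force maximizer of the per-coordinate marginal posterior over
# log(alpha): fine grid plus stats::optimize refinement. Independent of the
# closed-form / golden-section code paths in R/priors.R.
oracle_alpha <- function(s, q, prior, lo = -30, hi = 30, step = 0.01) {
  g <- seq(lo, hi, by = step)
  v <- alpha_objective(exp(g), s, q, prior)
  i <- which.max(v)
  opt <- stats::optimize(function(t) alpha_objective(exp(t), s, q, prior),
                         lower = g[max(1, i - 2)], upper = g[min(length(g), i + 2)],
                         maximum = TRUE, tol = 1e-12)
  best_val <- opt$objective
  list(alpha = if (best_val > 0) exp(opt$maximum) else Inf,
       value = max(best_val, 0))
}

# dense leave-one-out computation of (s, q) by explicit matrix inversion:
# C = X_act A^-1 X_act^T + B^-1, with column `drop_pos` of the active set
# removed when given.
oracle_sq <- function(x, Xact, alpha, B, yp, drop_pos = NULL) {
  if (!is.null(drop_pos)) {
    Xact <- Xact[, -drop_pos, drop = FALSE]
    alpha <- alpha[-drop_pos]
  }
  n <- length(B)
  C <- diag(1 / B, n)
  if (ncol(Xact) > 0) C <- C + Xact %*% (t(Xact) / alpha)
  Ci <- solve(C)
  list(s = as.numeric(t(x) %*% Ci %*% x),
       q = as.numeric(t(x) %*% Ci %*% yp))
}

# small random logistic instance with known coefficients
random_logistic <- function(n, k, beta = NULL, seed = 1) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * k), n, k))
  if (is.null(beta)) beta <- c(0, rnorm(k))
  p <- stats::plogis(as.vector(X %*% beta))
  list(X = X, y = stats::rbinom(n, 1, p), beta = beta, p = p)
}

# unit-norm scale a matrix's columns (the engine's internal scale)
unit_norm <- function(X) {
  cn <- sqrt(colSums(X^2))
  cn[cn == 0] <- 1
  X / rep(cn, each = nrow(X))
}
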