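# Laplace/MAP machinery for the logistic posterior: Newton-Raphson mode
# finding with step halving, the Gaussian (Laplace) covariance, and the
# pseudo-response that turns the problem into an equivalent weighted linear
# model.

# numerically safe Bernoulli log-likelihood from the linear predictor
bernoulli_loglik <- function(eta, y) {
  # log(1 + exp(eta)) computed without overflow
  lse <- ifelse(eta > 30, eta + log1p(exp(-eta)), log1p(exp(eta)))
  sum(y * eta - lse)
}

#' MAP estimate of logistic regression coefficients under Gaussian priors
#'
#' Maximizes the log posterior \eqn{\sum_i [y_i \log p_i + (1-y_i)\log(1-p_i)]
#' - \frac12 \beta^T A \beta} by Newton-Raphson with step halving, where `A`
#' is the diagonal matrix of prior precisions `alpha` (0 = flat prior, used
#' for the intercept). Returns the mode, the Laplace covariance
#' \eqn{\Sigma = (X^T B X + A)^{-1}} with \eqn{B = diag(p(1-p))} at the mode,
#' the IRLS weights and the fitted probabilities.
#'
#' @param X numeric matrix including the intercept column.
#' @param y binary response vector (0/1).
#' @param alpha prior precisions, one per column of `X` (0 allowed).
#' @param beta_init optional starting value (default 0).
#' @param tol convergence tolerance on the gradient infinity norm.
#' @param maxit maximum Newton iterations.
#' @param max_halving maximum step halvings per iteration.
#' @return list with `beta`, `Sigma`, `B` (diagonal weight vector), `p`,
#'   `loglik` (penalized log posterior at the mode), `iter` and `grad_norm`.
#' @export
map_estimate <- function(X, y, alpha, beta_init = NULL,
                         tol = 1e-6, maxit = 50, max_halving = 10) {
  X <- as.matrix(X)
  n <- nrow(X); kc <- ncol(X)
  stopifnot(length(y) == n, length(alpha) == kc, all(y %in% c(0, 1)))
  beta <- if (is.null(beta_init)) numeric(kc) else as.numeric(beta_init)
  obj <- function(b) {
    bernoulli_loglik(as.vector(X %*% b), y) - 0.5 * sum(alpha * b^2)
  }
  f <- obj(beta)
  grad_norm <- Inf
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    p <- stats::plogis(eta)
    g <- as.vector(crossprod(X, y - p)) - alpha * beta
    grad_norm <- max(abs(g))
    if (grad_norm <= tol) break
    b <- pmin(pmax(p * (1 - p), 1e-10), 0.25)
    Hm <- crossprod(X * sqrt(b)) + diag(alpha, kc)
    step <- tryCatch(solve(Hm, g),
                     error = function(e) stop("Hessian numerically singular in map_estimate"))
    lam <- 1
    ok <- FALSE
    for (h in seq_len(max_halving + 1)) {
      fnew <- obj(beta + lam * step)
      if (is.finite(fnew) && fnew >= f - 1e-12) { ok <- TRUE; break }
      lam <- lam / 2
    }
    if (!ok) break  # step-halving exhausted; gradient check below decides
    beta <- beta + lam * step
    f <- fnew
  }
  eta <- as.vector(X %*% beta)
  p <- stats::plogis(eta)
  g <- as.vector(crossprod(X, y - p)) - alpha * beta
  grad_norm <- max(abs(g))
  if (grad_norm > max(tol, 1e-4)) {
    cond <- structure(class = c("ebqtl_map_error", "error", "condition"),
                      list(message = sprintf(
                        "Newton-Raphson did not converge (gradient norm %.3g)",
                        grad_norm),
                        call = sys.call(-1), beta = beta))
    stop(cond)
  }
  b <- pmin(pmax(p * (1 - p), 1e-10), 0.25)
  Hm <- crossprod(X * sqrt(b)) + diag(alpha, kc)
  Sigma <- chol2inv(chol(Hm))
  list(beta = beta, Sigma = Sigma, B = b, p = p,
       loglik = obj(beta), iter = it, grad_norm = grad_norm)
}

#' Pseudo-response of the equivalent weighted linear model
#'
#' Forms \eqn{\hat y = X\beta_{MAP} + B^{-1}(y - p_{MAP})}, the working
#' response for which the Laplace approximation of the logistic posterior is
#' the exact Gaussian posterior of the linear model
#' \eqn{\hat y = X\beta + \epsilon}, \eqn{\epsilon \sim N(0, B^{-1})}.
#' Probabilities at 0 or 1 exactly (separation) are clipped to
#' `[1e-10, 1 - 1e-10]` with a warning before inverting `B`.
#'
#' @param X design matrix (including intercept).
#' @param beta_map MAP coefficients.
#' @param y binary response.
#' @param p_map fitted probabilities at the mode.
#' @param B optional IRLS weight vector `p(1-p)`; recomputed from the clipped
#'   probabilities when missing.
#' @return numeric pseudo-response vector.
#' @export
pseudo_response <- function(X, beta_map, y, p_map, B = NULL) {
  if (any(p_map <= 0 | p_map >= 1)) {
    warning("fitted probabilities at 0/1 (separation); clipping before forming B^-1")
  }
  p <- pmin(pmax(p_map, 1e-10), 1 - 1e-10)
  if (is.null(B)) B <- p * (1 - p)
  as.vector(X %*% beta_map) + (y - p) / B
}
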