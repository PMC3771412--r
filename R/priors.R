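# Hierarchical shrinkage priors on regression coefficients and the
# per-coordinate empirical-Bayes variance updates.
#
# Each coefficient beta_i ~ N(0, sigma_i^2) with alpha_i = 1/sigma_i^2.
#   NE:  sigma_i^2 ~ Exponential(lambda)         (marginally Laplace, LASSO-like)
#   NEG: sigma_i^2 ~ integral of Exponential(lambda) against lambda ~
#        Gamma(a, b), i.e. p(sigma^2) = (a/b) (sigma^2/b + 1)^-(a+1)
#   uniform: flat prior on sigma_i^2 (the RVM-like lambda -> 0 limit of NE)
#
# The per-coordinate log marginal posterior of alpha_i, given the sparsity
# and quality factors (s, q) of column i, is
#   L(alpha) = 1/2 [ log(alpha/(alpha+s)) + q^2/(alpha+s) ] + log p(1/alpha)
# normalized so that L(alpha -> Inf) = 0 (effect excluded).

#' Shrinkage prior specifications
#'
#' Construct the prior on the per-coefficient variances used by [eb_fit()].
#' `prior_ne()` is the two-level normal-exponential prior with rate `lambda`;
#' `prior_neg()` is the three-level normal-exponential-gamma prior with shape
#' `a` and inverse scale `b`; `prior_uniform()` is the flat
#' (relevance-vector-machine-like) prior, equal to the `lambda = 0` limit of
#' the NE prior.
#'
#' @param lambda exponential rate on the coefficient variances; `lambda > 0`
#'   (0 is allowed and equals the uniform prior).
#' @param a,b NEG shape and inverse scale; requires `a > -1.5` and `b > 0`.
#' @return An object of class `eb_prior`.
#' @export
prior_ne <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) || lambda < 0)
    stop("NE prior requires a single rate lambda >= 0")
  structure(list(family = "NE", lambda = as.numeric(lambda)), class = "eb_prior")
}

#' @rdname prior_ne
#' @export
prior_neg <- function(a, b) {
  if (!is.numeric(a) || length(a) != 1 || is.na(a) || a <= -1.5)
    stop("NEG prior requires shape a > -1.5")
  if (!is.numeric(b) || length(b) != 1 || is.na(b) || b <= 0)
    stop("NEG prior requires inverse scale b > 0")
  structure(list(family = "NEG", a = as.numeric(a), b = as.numeric(b)),
            class = "eb_prior")
}

#' @rdname prior_ne
#' @export
prior_uniform <- function() {
  structure(list(family = "uniform"), class = "eb_prior")
}

#' @export
print.eb_prior <- function(x, ...) {
  lab <- switch(x$family,
                NE = sprintf("NE (lambda = %g)", x$lambda),
                NEG = sprintf("NEG (a = %g, b = %g)", x$a, x$b),
                uniform = "uniform (RVM-like)")
  cat("<eb_prior>", lab, "\n")
  invisible(x)
}

#' Per-coordinate marginal posterior of a prior precision
#'
#' Evaluates the per-coordinate log marginal posterior
#' \eqn{L(\alpha) = \frac12[\log(\alpha/(\alpha+s)) + q^2/(\alpha+s)] +
#' \log p(\sigma^2 = 1/\alpha)}, normalized so that the excluded-effect limit
#' \eqn{\alpha \to \infty} has value 0. `s` and `q` are the sparsity and
#' quality factors of the candidate column. Vectorized over `alpha`, `s`, `q`.
#'
#' @param alpha prior precision(s), in `(0, Inf]`.
#' @param s,q sparsity and quality factors, `s > 0`.
#' @param prior an [prior_ne()] / [prior_neg()] / [prior_uniform()] object.
#' @return numeric vector of objective values (0 at `alpha = Inf`).
#' @export
alpha_objective <- function(alpha, s, q, prior) {
  base <- 0.5 * (log(alpha / (alpha + s)) + q^2 / (alpha + s))
  base[is.infinite(alpha)] <- 0
  pen <- switch(prior$family,
    NE = -prior$lambda / alpha,
    NEG = -(prior$a + 1) * log1p(1 / (prior$b * alpha)),
    uniform = 0)
  if (prior$family != "uniform") pen[is.infinite(alpha)] <- 0
  base + pen
}

#' Closed-form NE precision update
#'
#' Returns the unique global maximizer of the per-coordinate marginal
#' posterior under the normal-exponential prior. The effect is excluded
#' (`Inf` returned) unless \eqn{q^2 - s > 2\lambda}; otherwise the finite
#' maximizer is \eqn{\alpha^* = s[(s + 4\lambda) + \sqrt{\Delta}] /
#' [2(q^2 - s - 2\lambda)]} with \eqn{\Delta = s^2 + 8 \lambda q^2}. At
#' `lambda = 0` this reduces to the uniform-prior (RVM-like) solution
#' \eqn{s^2/(q^2 - s)}. Vectorized over `s` and `q`.
#'
#' @param s,q sparsity and quality factors (`s > 0`).
#' @param lambda NE rate, `lambda >= 0`.
#' @return numeric vector of optimal precisions (`Inf` = exclude).
#' @export
alpha_update_ne <- function(s, q, lambda) {
  if (any(s <= 0)) stop("sparsity factor s must be positive")
  if (lambda < 0) stop("lambda must be >= 0")
  out <- rep(Inf, length(s))
  inc <- (q^2 - s) > 2 * lambda
  if (any(inc)) {
    si <- s[inc]; qi <- q[inc]
    delta <- si^2 + 8 * lambda * qi^2
    out[inc] <- si * ((si + 4 * lambda) + sqrt(delta)) /
      (2 * (qi^2 - si - 2 * lambda))
  }
  out
}

#' NEG precision update by scalar search
#'
#' Maximizes the per-coordinate marginal posterior under the
#' normal-exponential-gamma prior over \eqn{\log\alpha} with a coarse grid
#' followed by golden-section refinement; returns `Inf` (exclude) when the
#' supremum is attained in the \eqn{\alpha\to\infty} limit. Vectorized over
#' `s` and `q`.
#'
#' @inheritParams alpha_update_ne
#' @param a,b NEG hyperparameters (`a > -1.5`, `b > 0`).
#' @return numeric vector of optimal precisions (`Inf` = exclude).
#' @export
alpha_update_neg <- function(s, q, a, b) {
  if (any(s <= 0)) stop("sparsity factor s must be positive")
  if (a <= -1.5 || b <= 0) stop("NEG prior requires a > -1.5 and b > 0")
  prior <- prior_neg(a, b)
  res <- neg_search(s, q, prior)
  ifelse(res$value > 0, res$alpha, Inf)
}

# vectorized grid + golden-section maximization of alpha_objective over
# log(alpha); returns list(alpha, value) of the best *finite* point
neg_search <- function(s, q, prior, lo = -25, hi = 30, step = 0.25) {
  grid <- seq(lo, hi, by = step)
  best_v <- rep(-Inf, length(s))
  best_g <- rep(lo, length(s))
  for (g in grid) {
    v <- alpha_objective(exp(g), s, q, prior)
    upd <- v > best_v
    best_v[upd] <- v[upd]
    best_g[upd] <- g
  }
  # golden-section on [best - step, best + step] in log alpha
  gr <- (sqrt(5) - 1) / 2
  a0 <- best_g - step; b0 <- best_g + step
  c0 <- b0 - gr * (b0 - a0); d0 <- a0 + gr * (b0 - a0)
  fc <- alpha_objective(exp(c0), s, q, prior)
  fd <- alpha_objective(exp(d0), s, q, prior)
  for (it in seq_len(70)) {
    left <- fc >= fd
    b0[left] <- d0[left]; d0[left] <- c0[left]; fd[left] <- fc[left]
    c0[left] <- b0[left] - gr * (b0[left] - a0[left])
    fc[left] <- alpha_objective(exp(c0[left]), s[left], q[left], prior)
    r <- !left
    a0[r] <- c0[r]; c0[r] <- d0[r]; fc[r] <- fd[r]
    d0[r] <- a0[r] + gr * (b0[r] - a0[r])
    fd[r] <- alpha_objective(exp(d0[r]), s[r], q[r], prior)
  }
  gstar <- (a0 + b0) / 2
  list(alpha = exp(gstar), value = alpha_objective(exp(gstar), s, q, prior))
}

# best finite alpha and objective value under any prior family; used by the
# greedy linear pass. For NE/uniform the closed form is exact.
alpha_best <- function(s, q, prior) {
  if (prior$family == "NEG") {
    res <- neg_search(s, q, prior)
    list(alpha = ifelse(res$value > 0, res$alpha, Inf),
         value = pmax(res$value, 0))
  } else {
    lam <- if (prior$family == "NE") prior$lambda else 0
    astar <- alpha_update_ne(s, q, lam)
    fin <- is.finite(astar)
    val <- numeric(length(s))
    if (any(fin)) val[fin] <- alpha_objective(astar[fin], s[fin], q[fin], prior)
    list(alpha = astar, value = val)
  }
}
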