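# The EBLASSO-NE / EBLASSO-NEG engine: greedy empirical-Bayes variance
# estimation on the weighted linear model that the Laplace approximation
# produces, alternated with Newton-Raphson MAP steps on the logistic
# posterior.
#
# Sparsity/quality bookkeeping follows the fast greedy scheme for sparse
# Bayesian linear models: for the model covariance C = X A^-1 X^T + B^-1
# (over the *included* effect columns only; the intercept lives solely in
# the Laplace step), every candidate column carries
#   S_i = x_i^T C^-1 x_i,   Q_i = x_i^T C^-1 y_pseudo
# computed through the Woodbury identity, never materializing the n x n
# inverse. The leave-one-out factors are s_i = a_i S_i/(a_i - S_i),
# q_i = a_i Q_i/(a_i - S_i) for included effects and s_i = S_i, q_i = Q_i
# otherwise. Candidate columns enter this machinery scaled to unit
# Euclidean norm, which is the scale the shrinkage hyperparameters act on;
# coefficient estimates are mapped back to the raw coding when reported.

#' Control parameters for [eb_fit()]
#'
#' @param tol_loglik outer convergence: absolute change of the penalized
#'   log-likelihood between consecutive Laplace iterations.
#' @param tol_alpha outer convergence: total `sum(|delta log alpha|)` across
#'   one greedy pass.
#' @param maxit_outer maximum Laplace (outer) iterations.
#' @param newton_tol,maxit_newton,max_halving Newton-Raphson controls for
#'   the MAP step (gradient infinity norm tolerance, iteration cap, step
#'   halvings).
#' @param accept_tol a greedy action must improve the marginal posterior by
#'   more than this to be accepted.
#' @param max_actions cap on accepted actions within one greedy pass.
#' @param df degrees of freedom for Wald p-values: `"residual"` uses
#'   `n - k_m - 1`, `"one"` uses 1 (the convention of some hierarchical GLM
#'   packages).
#' @param p_threshold significance threshold used when flagging effects.
#' @return list of class `eb_control`.
#' @export
eb_control <- function(tol_loglik = 1e-4, tol_alpha = 1e-3, maxit_outer = 200,
                       newton_tol = 1e-6, maxit_newton = 50, max_halving = 10,
                       accept_tol = 1e-6, max_actions = 1000,
                       df = c("residual", "one"), p_threshold = 0.05) {
  df <- match.arg(df)
  structure(as.list(environment()), class = "eb_control")
}

# posterior covariance over included effect columns only (no intercept)
sigma_eff <- function(Xact, alpha, B) {
  if (ncol(Xact) == 0) return(matrix(0, 0, 0))
  M <- crossprod(Xact * sqrt(B)) + diag(alpha, ncol(Xact))
  chol2inv(chol(M))
}

# S and Q for every candidate column of a provider. For the streamed
# epistatic expansion each pass costs a handful of m x m GEMMs; no n x k
# matrix is formed.
sq_all <- function(prov, Xact, Sig, B, yp) {
  u <- B * yp
  km <- ncol(Xact)
  cn <- prov$norms
  if (prov$type == "design") {
    X <- prov$X
    Sdiag <- colSums(X * (B * X)) / cn^2
    Q0 <- as.vector(crossprod(X, u)) / cn
    if (km > 0) {
      P <- crossprod(Xact, B * X) / rep(cn, each = km)
      R <- chol(Sig)
      S <- Sdiag - colSums((R %*% P)^2)
      v <- Sig %*% crossprod(Xact, u)
      Q <- Q0 - as.vector(crossprod(P, v))
    } else {
      S <- Sdiag; Q <- Q0
    }
    return(list(S = pmax(S, 1e-12), Q = Q))
  }
  x <- prov$x
  Sdiag <- colSums(x * (B * x))
  Q0 <- as.vector(crossprod(x, u))
  if (prov$epistasis) {
    xsq <- prov$xsq
    ij <- cbind(prov$j1, prov$j2)
    Sdiag <- c(Sdiag, crossprod(xsq, B * xsq)[ij])
    Q0 <- c(Q0, crossprod(x, u * x)[ij])
  }
  Sdiag <- Sdiag / cn^2
  Q0 <- Q0 / cn
  if (km > 0) {
    P <- matrix(0, km, prov$k)
    for (a in seq_len(km)) {
      w <- B * Xact[, a]
      pa <- as.vector(crossprod(x, w))
      if (prov$epistasis) pa <- c(pa, crossprod(x, w * x)[cbind(prov$j1, prov$j2)])
      P[a, ] <- pa / cn
    }
    R <- chol(Sig)
    S <- Sdiag - colSums((R %*% P)^2)
    v <- Sig %*% crossprod(Xact, u)
    Q <- Q0 - as.vector(crossprod(P, v))
  } else {
    S <- Sdiag; Q <- Q0
  }
  list(S = pmax(S, 1e-12), Q = Q)
}

# x_j^T v for every candidate column (unit-norm scale)
prov_xtv <- function(prov, v) {
  if (prov$type == "design") {
    return(as.vector(crossprod(prov$X, v)) / prov$norms)
  }
  out <- as.vector(crossprod(prov$x, v))
  if (prov$epistasis) {
    out <- c(out, crossprod(prov$x, v * prov$x)[cbind(prov$j1, prov$j2)])
  }
  out / prov$norms
}

#' Sparsity and quality factors of a candidate effect column
#'
#' Computes \eqn{s_i = x_i^T C_{-i}^{-1} x_i} and
#' \eqn{q_i = x_i^T C_{-i}^{-1} \hat y} for one candidate column, where
#' \eqn{C = X A^{-1} X^T + B^{-1}} is built from the currently included
#' effect columns and \eqn{C_{-i}} excludes effect `i`. For an excluded
#' column `s = S`, `q = Q`; for an included one the capital-letter factors
#' are converted through \eqn{s = \alpha S/(\alpha - S)},
#' \eqn{q = \alpha Q/(\alpha - S)}. The inverse of `C` is applied through
#' the Woodbury identity. Columns are used exactly as given (no rescaling).
#'
#' @param x candidate column (length-n numeric).
#' @param model an active model as returned by [eb_active()].
#' @param included_at position of `x` within `model$alpha` when `x` is one
#'   of the included columns, `NULL` otherwise.
#' @return list with `s`, `q`, `S`, `Q` and `degenerate` (`TRUE` when
#'   `alpha <= S`, which flags the effect for deletion).
#' @export
sq_statistics <- function(x, model, included_at = NULL) {
  stopifnot(inherits(model, "eb_active"))
  B <- model$B; yp <- model$y_pseudo; Xact <- model$X
  Sig <- sigma_eff(Xact, model$alpha, B)
  w <- B * x
  if (ncol(Xact) > 0) {
    t1 <- crossprod(Xact, w)
    S <- sum(x * w) - as.vector(crossprod(t1, Sig %*% t1))
    Q <- sum(w * yp) - as.vector(crossprod(t1, Sig %*% crossprod(Xact, B * yp)))
  } else {
    S <- sum(x * w)
    Q <- sum(w * yp)
  }
  if (!is.null(included_at)) {
    a <- model$alpha[included_at]
    den <- a - S
    if (den <= 0) {
      return(list(s = NA_real_, q = NA_real_, S = S, Q = Q, degenerate = TRUE))
    }
    list(s = a * S / den, q = a * Q / den, S = S, Q = Q, degenerate = FALSE)
  } else {
    list(s = S, q = Q, S = S, Q = Q, degenerate = FALSE)
  }
}

#' Active model of the equivalent linear problem
#'
#' Bundles the state the greedy pass operates on: the included effect
#' columns, their prior precisions, the IRLS weights and the pseudo-response
#' from the current Laplace step.
#'
#' @param X n x k_m matrix of included effect columns (no intercept).
#' @param alpha prior precisions of the included effects.
#' @param B IRLS weight vector `p(1-p)`.
#' @param y_pseudo pseudo-response from [pseudo_response()].
#' @param idx optional candidate indices of the included columns.
#' @return object of class `eb_active`.
#' @export
eb_active <- function(X, alpha, B, y_pseudo, idx = NULL) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(alpha), nrow(X) == length(B),
            length(B) == length(y_pseudo), all(alpha > 0), all(B > 0))
  structure(list(X = X, alpha = as.numeric(alpha), B = as.numeric(B),
                 y_pseudo = as.numeric(y_pseudo), idx = idx),
            class = "eb_active")
}

# dense evaluation of the log marginal posterior of alpha (test oracle path;
# n must be small). Normalized like alpha_objective: excluded effects
# contribute nothing.
eb_objective_dense <- function(Xact, alpha, B, yp, prior) {
  n <- length(B)
  C <- diag(1 / B, n)
  if (ncol(Xact) > 0) C <- C + Xact %*% (t(Xact) / alpha)
  pen <- switch(prior$family,
    NE = sum(-prior$lambda / alpha),
    NEG = sum(-(prior$a + 1) * log1p(1 / (prior$b * alpha))),
    uniform = 0)
  -0.5 * (determinant(C, logarithm = TRUE)$modulus[1] +
            sum(yp * solve(C, yp))) + pen
}

# screened precision update for all candidates: exact for NE/uniform; for
# NEG a coarse log-grid screen keeps only plausible candidates (and any in
# `exact_mask`) for the exact search.
alpha_best_all <- function(s, q, prior, exact_mask = NULL) {
  if (prior$family != "NEG") return(alpha_best(s, q, prior))
  coarse <- rep(-Inf, length(s))
  for (g in seq(-20, 25, by = 0.5)) {
    coarse <- pmax(coarse, alpha_objective(exp(g), s, q, prior))
  }
  keep <- coarse > -0.1
  if (!is.null(exact_mask)) keep <- keep | exact_mask
  alpha <- rep(Inf, length(s)); value <- numeric(length(s))
  if (any(keep)) {
    res <- alpha_best(s[keep], q[keep], prior)
    alpha[keep] <- res$alpha; value[keep] <- res$value
  }
  list(alpha = alpha, value = value)
}

# One greedy pass over the candidate columns. Included-effect actions
# (re-estimate / delete) are decided on exact small-matrix S/Q; additions
# are proposed from a cached full-candidate sweep and every proposal is
# re-verified exactly before acceptance (a fresh sweep is required before
# the pass may conclude that no addition improves the objective). Every
# accepted action therefore carries an exactly computed positive gain and
# the marginal posterior is non-decreasing across accepted actions.
eb_pass_core <- function(prov, idx, alpha, B, yp, prior, control) {
  n_add <- 0L; n_del <- 0L; dalpha <- 0
  events <- character(0)
  gains <- numeric(0)
  actions <- 0L
  atol <- control$accept_tol

  Xact <- prov_cols(prov, idx)
  Sig <- sigma_eff(Xact, alpha, B)
  u1 <- crossprod(Xact, B * yp)

  rebuild <- function() {
    Xact <<- prov_cols(prov, idx)
    Sig <<- sigma_eff(Xact, alpha, B)
    u1 <<- crossprod(Xact, B * yp)
  }

  record <- function(what, gain) {
    events <<- c(events, what)
    gains <<- c(gains, gain)
    actions <<- actions + 1L
  }

  # exact S, Q of one candidate under the current model
  exact_sq <- function(j) {
    xj <- as.vector(prov_cols(prov, j))
    w <- B * xj
    if (length(idx)) {
      t1 <- crossprod(Xact, w)
      list(S = max(sum(xj * w) - as.vector(crossprod(t1, Sig %*% t1)), 1e-12),
           Q = sum(w * yp) - as.vector(crossprod(t1, Sig %*% u1)))
    } else {
      list(S = max(sum(xj * w), 1e-12), Q = sum(w * yp))
    }
  }

  # re-estimate / delete included effects until none improves
  included_cycle <- function() {
    repeat {
      if (!length(idx) || actions >= control$max_actions) return()
      M <- crossprod(Xact, B * Xact)
      MS <- M %*% Sig
      S <- pmax(diag(M) - rowSums(MS * M), 1e-12)
      Q <- as.vector(u1 - MS %*% u1)
      den <- alpha - S
      bad <- which(den <= 1e-12)
      if (length(bad)) {  # numerically degenerate: forced deletion
        pos <- bad[1]
        record(sprintf("delete %d (degenerate)", idx[pos]), NA_real_)
        idx <<- idx[-pos]; alpha <<- alpha[-pos]; n_del <<- n_del + 1L
        rebuild()
        next
      }
      s <- alpha * S / den
      q <- alpha * Q / den
      ab <- alpha_best(s, q, prior)
      fcur <- alpha_objective(alpha, s, q, prior)
      gain <- ifelse(is.finite(ab$alpha), ab$value - fcur, -fcur)
      pos <- which.max(gain)
      if (gain[pos] <= atol) return()
      j <- idx[pos]
      if (is.finite(ab$alpha[pos])) {
        record(sprintf("re-estimate %d", j), gain[pos])
        dalpha <<- dalpha + abs(log(ab$alpha[pos]) - log(alpha[pos]))
        alpha[pos] <<- ab$alpha[pos]
        Sig <<- sigma_eff(Xact, alpha, B)
      } else {
        record(sprintf("delete %d", j), gain[pos])
        idx <<- idx[-pos]; alpha <<- alpha[-pos]; n_del <<- n_del + 1L
        rebuild()
      }
    }
  }

  included_cycle()
  repeat {
    if (actions >= control$max_actions) break
    sq <- sq_all(prov, Xact, Sig, B, yp)
    ab <- alpha_best_all(sq$S, sq$Q, prior)
    gain_stale <- ab$value
    gain_stale[idx] <- -Inf  # included effects are handled by the cycle
    gain_stale[!is.finite(ab$alpha)] <- -Inf
    ord <- order(gain_stale, decreasing = TRUE)
    accepted_any <- FALSE
    for (t in ord) {
      if (actions >= control$max_actions) break
      if (gain_stale[t] <= atol) break
      if (t %in% idx) next
      # verify against the *current* model before accepting
      e <- exact_sq(t)
      ab1 <- alpha_best(e$S, e$Q, prior)
      if (is.finite(ab1$alpha) && ab1$value > atol) {
        record(sprintf("add %d (alpha=%.4g)", t, ab1$alpha), ab1$value)
        idx <- c(idx, t); alpha <- c(alpha, ab1$alpha); n_add <- n_add + 1L
        rebuild()
        accepted_any <- TRUE
        included_cycle()
      }
    }
    if (!accepted_any) break
  }
  list(idx = idx, alpha = alpha, n_add = n_add, n_del = n_del,
       dalpha = dalpha, events = events, gains = gains)
}

#' One greedy empirical-Bayes pass over the candidate columns
#'
#' Applies add / delete / re-estimate actions on the equivalent linear model
#' until no action increases the log marginal posterior of the precisions.
#' Exposed mainly for testing and step-by-step inspection; [eb_fit()] drives
#' this inside the Laplace loop. Candidate columns are used on the unit-norm
#' scale; the returned state holds the scaled columns.
#'
#' @param model an [eb_active()] state whose `idx` indexes columns of
#'   `candidates`.
#' @param candidates n x k matrix of all candidate effect columns.
#' @param prior an `eb_prior`.
#' @param control an [eb_control()].
#' @return Updated `eb_active` state; attribute `"events"` lists accepted
#'   actions, `"gains"` their exact objective improvements, and `"n_add"`,
#'   `"n_del"`, `"dalpha"` summarize the pass.
#' @export
eb_linear_pass <- function(model, candidates, prior, control = eb_control()) {
  stopifnot(inherits(model, "eb_active"))
  prov <- new_provider_matrix(as.matrix(candidates))
  idx <- model$idx
  if (is.null(idx)) stop("model$idx must give candidate indices of included columns")
  res <- eb_pass_core(prov, idx, model$alpha, model$B, model$y_pseudo,
                      prior, control)
  out <- eb_active(prov_cols(prov, res$idx), res$alpha, model$B,
                   model$y_pseudo, idx = res$idx)
  attr(out, "events") <- res$events
  attr(out, "gains") <- res$gains
  attr(out, "n_add") <- res$n_add
  attr(out, "n_del") <- res$n_del
  attr(out, "dalpha") <- res$dalpha
  out
}

#' Initialize the active set with the single best-correlated column
#'
#' Picks the candidate column maximizing \eqn{|x_i^T (y - p_0)|} with
#' \eqn{p_0} the sample prevalence, estimates its coefficient by least
#' squares on the centered (unit-norm scaled) column, and sets its prior
#' precision to \eqn{1/\hat\beta^2}; all other precisions are notionally
#' infinite.
#'
#' @param X candidate matrix (effect columns, no intercept) or a `qtl_geno`.
#' @param y binary response.
#' @return list with `idx`, `alpha`, `beta` and `p0`.
#' @export
eb_initialize <- function(X, y) {
  if (length(unique(y)) < 2) stop("response is constant; nothing to model")
  prov <- as_provider(X, epistasis = FALSE)
  init_core(prov, y)
}

init_core <- function(prov, y) {
  p0 <- mean(y)
  r <- y - p0
  ip <- abs(prov_xtv(prov, r))
  ord <- order(ip, decreasing = TRUE)
  for (j in ord) {
    xj <- as.vector(prov_cols(prov, j))
    xt <- xj - mean(xj)
    ss <- sum(xt^2)
    if (ss > 0) {
      beta <- sum(xt * r) / ss
      if (beta != 0) {
        return(list(idx = j, alpha = 1 / beta^2, beta = beta, p0 = p0))
      }
    }
  }
  stop("no candidate column with variation found")
}

as_provider <- function(x, epistasis = FALSE) {
  if (inherits(x, "eb_provider")) return(x)
  if (inherits(x, "qtl_geno")) {
    if (anyNA(x$x)) stop("genotypes contain missing calls; run impute_missing() first")
    return(new_provider(x$x, epistasis = epistasis, pos = x$pos))
  }
  X <- as.matrix(x)
  keys <- attr(x, "keys")
  if (!is.null(keys) && keys$kind[1] == "intercept") {
    X <- X[, -1, drop = FALSE]
    keys <- keys[-1, ]
    return(new_provider_matrix(X, keys = keys))
  }
  if (epistasis) return(new_provider(X, epistasis = TRUE))
  new_provider_matrix(X, keys = keys)
}

new_provider_matrix <- function(X, keys = NULL, pos = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(keys)) {
    keys <- tibble::tibble(kind = rep("main", ncol(X)),
                           locus1 = seq_len(ncol(X)),
                           locus2 = NA_integer_)
  }
  norms <- sqrt(colSums(X^2))
  norms[norms == 0] <- 1
  structure(list(type = "design", X = X, n = nrow(X), k = ncol(X),
                 keys = keys, norms = norms, pos = pos),
            class = "eb_provider")
}

#' Wald summaries of retained effects
#'
#' Computes \eqn{t_i = \hat\beta_i / \Sigma_{ii}^{1/2}} and two-sided
#' p-values from the Student t reference distribution.
#'
#' @param beta coefficient estimates.
#' @param Sigma posterior covariance (its diagonal supplies the squared
#'   standard errors).
#' @param n sample size.
#' @param k_m number of retained effects (excluding the intercept).
#' @param df `"residual"` for `max(1, n - k_m - 1)` degrees of freedom or
#'   `"one"` for 1.
#' @return tibble with `estimate`, `se`, `statistic`, `p_value`.
#' @export
wald_summary <- function(beta, Sigma, n, k_m, df = c("residual", "one")) {
  df <- match.arg(df)
  se <- sqrt(diag(as.matrix(Sigma)))
  stat <- ifelse(se > 0, beta / se, 0)
  nu <- if (df == "one") 1 else max(1, n - k_m - 1)
  p <- 2 * stats::pt(-abs(stat), df = nu)
  tibble::tibble(estimate = as.numeric(beta), se = se,
                 statistic = as.numeric(stat), p_value = pmin(p, 1))
}
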