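#' Fit a sparse Bayesian logistic QTL model by empirical Bayes
#'
#' The main entry point: fits the multiple-QTL logistic regression model
#' with main (and optionally pairwise epistatic) marker effects under an NE,
#' NEG or uniform shrinkage prior. Inference alternates a Newton-Raphson
#' Laplace step on the logistic posterior with greedy empirical-Bayes
#' updates of the per-effect prior variances on the equivalent weighted
#' linear model, starting from a single best-correlated column, until no
#' effect is added or deleted, the likelihood stabilizes and the precisions
#' stop moving. The epistatic expansion (k = 1 + m + m(m-1)/2 candidate
#' effects) is streamed in blocks, so the full design is never materialized.
#'
#' @param x a [qtl_geno] object, a plain marker matrix (coded genotypes), or
#'   a dense design from [build_design()].
#' @param y binary phenotype vector (0/1), one entry per individual.
#' @param prior an [prior_ne()], [prior_neg()] or [prior_uniform()] object.
#' @param epistasis expand pairwise product effects? Ignored when `x` is
#'   already a design matrix.
#' @param control an [eb_control()].
#' @return An object of class `eb_fit` with components
#'   \describe{
#'     \item{effects}{tibble of retained effects: kind, loci, positions
#'       (cM, when known), `estimate`, `se`, `statistic`, `p_value`,
#'       `alpha`, `significant`.}
#'     \item{intercept}{intercept estimate and standard error.}
#'     \item{log}{per-iteration trace (log-likelihood, model size, actions).}
#'     \item{converged}{logical.}
#'   }
#'   Use [generics::tidy()] / [generics::glance()] / `autoplot()` on it.
#' @examples
#' set.seed(1)
#' G <- simulate_f2_genotypes(n = 150, m = 30, spacing_cm = 5)
#' truth <- tibble::tibble(kind = "main", locus1 = c(5L, 20L),
#'                         locus2 = NA_integer_, beta = c(1.5, -1.5))
#' y <- simulate_phenotype(G, truth)
#' fit <- eb_fit(G, y, prior_neg(0.01, 6))
#' tidy(fit)
#' @export
eb_fit <- function(x, y, prior, epistasis = FALSE, control = eb_control()) {
  stopifnot(inherits(prior, "eb_prior"), inherits(control, "eb_control"))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("phenotype must be coded 0/1")
  prov <- as_provider(x, epistasis = epistasis)
  n <- prov$n
  if (length(y) != n) stop("length(y) must equal the number of individuals")
  if (length(unique(y)) < 2) stop("phenotype has a single class; nothing to map")

  init <- init_core(prov, y)
  idx <- init$idx
  alpha <- init$alpha
  beta_warm <- c(stats::qlogis(init$p0), init$beta)

  log_rows <- vector("list", control$maxit_outer)
  all_events <- character(0)
  ll_prev <- -Inf
  converged <- FALSE
  oscillating <- FALSE
  mp <- NULL
  best <- list(ll = -Inf, idx = idx, alpha = alpha, warm = beta_warm)
  seen <- new.env(parent = emptyenv())  # active-set signatures (cycle guard)

  for (iter in seq_len(control$maxit_outer)) {
    Xact <- prov_cols(prov, idx)
    Xfull <- cbind(1, Xact)
    mp <- map_estimate(Xfull, y, c(0, alpha), beta_init = beta_warm,
                       tol = control$newton_tol, maxit = control$maxit_newton,
                       max_halving = control$max_halving)
    yp <- pseudo_response(Xfull, mp$beta, y, mp$p, mp$B)
    if (mp$loglik > best$ll) {
      best <- list(ll = mp$loglik, idx = idx, alpha = alpha, warm = mp$beta)
    }
    pass <- eb_pass_core(prov, idx, alpha, mp$B, yp, prior, control)
    changed <- pass$n_add + pass$n_del
    log_rows[[iter]] <- tibble::tibble(
      iter = iter, loglik = mp$loglik, k_m = length(pass$idx),
      adds = pass$n_add, deletes = pass$n_del, dalpha = pass$dalpha)
    all_events <- c(all_events, pass$events)

    done <- changed == 0 &&
      abs(mp$loglik - ll_prev) < control$tol_loglik &&
      pass$dalpha < control$tol_alpha
    ll_prev <- mp$loglik

    # carry coefficients over to the new active set as warm start
    old_beta <- stats::setNames(mp$beta[-1], as.character(idx))
    idx <- pass$idx
    alpha <- pass$alpha
    bw <- old_beta[as.character(idx)]
    bw[is.na(bw)] <- 0
    beta_warm <- c(mp$beta[1], unname(bw))

    if (done) { converged <- TRUE; break }

    # cycle guard: a structurally changed active set revisiting an earlier
    # configuration repeatedly means the Laplace and selection steps are
    # flip-flopping on a borderline effect; keep the best iterate instead
    # of grinding to maxit_outer
    if (changed > 0) {
      sig <- paste(c("set", sort(idx)), collapse = ",")
      cnt <- (if (is.null(seen[[sig]])) 0L else seen[[sig]]) + 1L
      seen[[sig]] <- cnt
      if (cnt >= 3L) { oscillating <- TRUE; break }
    }
  }
  if (!converged) {
    if (oscillating) {
      warning("eb_fit oscillated between active sets; returning the best iterate")
    } else {
      warning("eb_fit reached maxit_outer without satisfying all convergence criteria")
    }
    idx <- best$idx
    alpha <- best$alpha
    beta_warm <- best$warm
  }

  Xact <- prov_cols(prov, idx)
  Xfull <- cbind(1, Xact)
  mp <- map_estimate(Xfull, y, c(0, alpha), beta_init = beta_warm,
                     tol = control$newton_tol, maxit = control$maxit_newton,
                     max_halving = control$max_halving)
  k_m <- length(idx)
  ws <- wald_summary(mp$beta, mp$Sigma, n, k_m, df = control$df)
  # the engine works on unit-norm scaled columns; report on the raw coding
  cn <- prov_norms(prov, idx)
  ws$estimate[-1] <- ws$estimate[-1] / cn
  ws$se[-1] <- ws$se[-1] / cn
  keys <- prov_keys(prov, idx)
  pos <- prov$pos
  effects <- dplyr::bind_cols(keys, ws[-1, ])
  effects$alpha <- alpha
  effects$pos1 <- if (!is.null(pos)) pos[effects$locus1] else NA_real_
  effects$pos2 <- if (!is.null(pos)) pos[effects$locus2] else NA_real_
  effects$significant <- effects$p_value <= control$p_threshold
  effects <- effects[order(effects$locus1, effects$locus2,
                           method = "radix", na.last = TRUE), ]
  effects <- effects[, c("kind", "locus1", "locus2", "pos1", "pos2",
                         "estimate", "se", "statistic", "p_value",
                         "alpha", "significant")]

  structure(list(
    effects = tibble::as_tibble(effects),
    intercept = ws[1, c("estimate", "se")],
    prior = prior,
    control = control,
    n = n, k = prov_ncol(prov), k_m = k_m,
    loglik = mp$loglik,
    log = dplyr::bind_rows(log_rows[!vapply(log_rows, is.null, TRUE)]),
    events = all_events,
    converged = converged,
    oscillating = oscillating,
    idx = idx, alpha = alpha,
    beta = mp$beta, Sigma = mp$Sigma),
    class = "eb_fit")
}

#' @export
print.eb_fit <- function(x, ...) {
  lab <- switch(x$prior$family,
                NE = sprintf("EBLASSO-NE (lambda = %g)", x$prior$lambda),
                NEG = sprintf("EBLASSO-NEG (a = %g, b = %g)", x$prior$a, x$prior$b),
                uniform = "EB logistic regression, uniform prior (RVM-like)")
  cat(sprintf("%s: %d of %d candidate effects retained (n = %d)\n",
              lab, x$k_m, x$k, x$n))
  cat(sprintf("  %d significant at p <= %g; penalized loglik %.3f; %s\n",
              sum(x$effects$significant), x$control$p_threshold, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  print(x$effects, n = 20)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the retained effects of an EBLASSO fit
#'
#' @param x an `eb_fit`.
#' @param significant_only keep only effects with `p_value <= p_threshold`?
#' @param ... unused.
#' @return tibble, one row per retained effect.
#' @export
tidy.eb_fit <- function(x, significant_only = FALSE, ...) {
  out <- x$effects
  if (significant_only) out <- dplyr::filter(out, .data$significant)
  out
}

#' One-row model summary of an EBLASSO fit
#'
#' @param x an `eb_fit`.
#' @param ... unused.
#' @export
glance.eb_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, k_candidates = x$k, k_retained = x$k_m,
    n_significant = sum(x$effects$significant),
    loglik = x$loglik,
    iterations = nrow(x$log),
    converged = x$converged,
    prior = x$prior$family)
}

#' Effect plot for an EBLASSO fit
#'
#' Plots retained main effects along the genome (estimate versus position,
#' with +/- 2 SE bars); epistatic effects, if any, are drawn as points at
#' the midpoint of their two loci with a distinct shape.
#'
#' @param object an `eb_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.eb_fit <- function(object, ...) {
  eff <- object$effects
  eff$x <- ifelse(is.na(eff$pos1), as.numeric(eff$locus1), eff$pos1)
  eff$x[eff$kind == "epistatic"] <-
    (eff$x[eff$kind == "epistatic"] +
       ifelse(is.na(eff$pos2[eff$kind == "epistatic"]),
              as.numeric(eff$locus2[eff$kind == "epistatic"]),
              eff$pos2[eff$kind == "epistatic"])) / 2
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$x, y = .data$estimate,
                                    shape = .data$kind,
                                    colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - 2 * .data$se,
                                        ymax = .data$estimate + 2 * .data$se),
                           width = 0) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "position (cM)", y = "effect estimate",
                  title = "Retained QTL effects") +
    ggplot2::theme_minimal()
}
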