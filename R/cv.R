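# Ten-fold cross-validation of the shrinkage hyperparameters by average
# predictive log-likelihood (per-observation, so values are comparable
# across sample sizes; for a binary outcome the ceiling is 0 and a coin-flip
# predictor scores -log 2).

# deterministic stratified fold assignment: depends only on (y, n_folds, seed)
cv_folds <- function(y, n_folds, seed) {
  n <- length(y)
  fold <- integer(n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  for (cls in sort(unique(y))) {
    ii <- which(y == cls)
    fold[ii] <- sample(rep_len(seq_len(n_folds), length(ii)))
  }
  fold
}

#' Cross-validated predictive log-likelihood of one prior setting
#'
#' Splits the data into `n_folds` class-stratified folds (formed once from
#' `seed`), fits the model on each training part and scores the held-out
#' part by the mean per-observation Bernoulli log-likelihood of the fitted
#' probabilities.
#'
#' @param x genotypes ([qtl_geno] or marker matrix).
#' @param y binary phenotype.
#' @param prior an `eb_prior`.
#' @param epistasis expand pairwise effects?
#' @param n_folds number of folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @param control an [eb_control()].
#' @return list with `logL` (mean across folds), `ste` (standard error
#'   across folds) and the per-fold values `fold_logL`.
#' @export
cv_loglik <- function(x, y, prior, epistasis = FALSE, n_folds = 10, seed = 1,
                      control = eb_control()) {
  stopifnot(n_folds >= 2)
  y <- as.numeric(y)
  xm <- if (inherits(x, "qtl_geno")) x$x else as.matrix(x)
  pos <- if (inherits(x, "qtl_geno")) x$pos else NULL
  fold <- cv_folds(y, n_folds, seed)
  per_fold <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) {
      # cannot happen with stratified folds unless a class is tiny
      warning("single-class training fold; refolding with a shifted seed")
      fold <- cv_folds(y, n_folds, seed + 104729L)
      tr <- fold != f
    }
    Gtr <- qtl_geno(xm[tr, , drop = FALSE], pos = pos)
    fit <- eb_fit(Gtr, y[tr], prior, epistasis = epistasis, control = control)
    eta <- rep(fit$intercept$estimate, sum(!tr))
    if (fit$k_m > 0) {
      for (r in seq_len(nrow(fit$effects))) {
        xi <- xm[!tr, fit$effects$locus1[r]]
        if (fit$effects$kind[r] == "epistatic") {
          xi <- xi * xm[!tr, fit$effects$locus2[r]]
        }
        eta <- eta + fit$effects$estimate[r] * xi
      }
    }
    yt <- y[!tr]
    per_fold[f] <- bernoulli_loglik(eta, yt) / length(yt)
  }
  list(logL = mean(per_fold), ste = stats::sd(per_fold) / sqrt(n_folds),
       fold_logL = per_fold)
}

#' Two-stage cross-validation grid for the NE rate
#'
#' Stage 1 starts from \eqn{\lambda_{max} = 1.5 \max_j |x_j^T(y - p_0)|}
#' (at which the fitted model typically keeps a single effect) and descends
#' to 0.001 with a log-step of 0.35, picking the rate with the best
#' cross-validated log-likelihood; stage 2 re-scans ten equally spaced
#' values in the length-0.01 interval centered at the stage-1 winner.
#'
#' @inheritParams cv_loglik
#' @return list with `lambda` (the winner), `logL`, and the visited `grid`
#'   tibble (`stage`, `lambda`, `logL`, `ste`).
#' @export
tune_ne <- function(x, y, epistasis = FALSE, n_folds = 10, seed = 1,
                    control = eb_control()) {
  prov <- as_provider(x, epistasis = epistasis)
  y <- as.numeric(y)
  lam_lasso <- max(abs(prov_xtv(prov, y - mean(y))))
  lam_max <- 1.5 * lam_lasso
  stage1 <- exp(seq(log(lam_max), log(0.001), by = -0.35))
  ev <- function(lams, stage) {
    purrr_map <- lapply(lams, function(l) {
      r <- cv_loglik(x, y, prior_ne(l), epistasis, n_folds, seed, control)
      tibble::tibble(stage = stage, lambda = l, logL = r$logL, ste = r$ste)
    })
    dplyr::bind_rows(purrr_map)
  }
  g1 <- ev(stage1, 1L)
  l1 <- g1$lambda[which.max(g1$logL)]
  stage2 <- seq(max(l1 - 0.005, 1e-6), l1 + 0.005, length.out = 10)
  g2 <- ev(stage2, 2L)
  grid <- dplyr::bind_rows(g1, g2)
  best <- grid[which.max(grid$logL), ]
  list(lambda = best$lambda, logL = best$logL, grid = grid)
}

#' Three-step cross-validation grid for the NEG hyperparameters
#'
#' Step (i) scans the diagonal a = b in {0.001, 0.01, 0.1, 1}; step (ii)
#' fixes b at the winner and scans a over
#' {-0.5, -0.4, -0.3, -0.2, -0.1, -0.01, 0.01, 0.05, 0.1, 0.5, 1}; step
#' (iii) fixes a and scans b from 0.01 to 10 (log-steps of one decade below
#' 1, unit steps above). Settings already evaluated are cached, not re-fit.
#'
#' @inheritParams cv_loglik
#' @return list with `a`, `b`, `logL` and the visited `grid` tibble
#'   (`stage`, `a`, `b`, `logL`, `ste`).
#' @export
tune_neg <- function(x, y, epistasis = FALSE, n_folds = 10, seed = 1,
                     control = eb_control()) {
  y <- as.numeric(y)
  cache <- new.env(parent = emptyenv())
  ev1 <- function(a, b) {
    key <- sprintf("%.10g|%.10g", a, b)
    if (!is.null(cache[[key]])) return(cache[[key]])
    r <- cv_loglik(x, y, prior_neg(a, b), epistasis, n_folds, seed, control)
    cache[[key]] <- r
    r
  }
  ev <- function(av, bv, stage) {
    rows <- mapply(function(a, b) {
      r <- ev1(a, b)
      tibble::tibble(stage = stage, a = a, b = b, logL = r$logL, ste = r$ste)
    }, av, bv, SIMPLIFY = FALSE)
    dplyr::bind_rows(rows)
  }
  diag_vals <- c(0.001, 0.01, 0.1, 1)
  g1 <- ev(diag_vals, diag_vals, 1L)
  b1 <- g1$b[which.max(g1$logL)]
  a_grid <- c(-0.5, -0.4, -0.3, -0.2, -0.1, -0.01, 0.01, 0.05, 0.1, 0.5, 1)
  g2 <- ev(a_grid, rep(b1, length(a_grid)), 2L)
  a2 <- g2$a[which.max(g2$logL)]
  # log-decade steps up to 1, then unit steps from 1 to 10 (b = 1 appears in
  # both series; the cache ensures it is fitted only once)
  b_grid <- c(0.01, 0.1, 1, seq(1, 10))
  g3 <- ev(rep(a2, length(b_grid)), b_grid, 3L)
  grid <- dplyr::bind_rows(g1, g2, g3)
  best <- grid[which.max(grid$logL), ]
  list(a = best$a, b = best$b, logL = best$logL, grid = grid)
}
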