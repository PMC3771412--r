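# Detection evaluation against a simulated truth table, the single-locus
# logistic baseline scan, and the post-selection unpenalized refit.

#' Score detected effects against a truth table
#'
#' A detected main effect is a true positive iff some true main-effect QTL
#' lies within `window_cm` of it; several detections matching the same truth
#' entry are merged and counted once. A detected epistatic pair matches a
#' true pair iff both of its loci are within `window_cm` of the pair's loci
#' (order-free); pairs are assigned to truth pairs greedily by smallest
#' total distance. Anything unmatched is a false positive.
#'
#' @param detections tibble of detected effects with columns `kind`
#'   ("main"/"epistatic"), `locus1`, `locus2` — e.g.
#'   `tidy(fit, significant_only = TRUE)`.
#' @param truth truth table (see [builtin_truth()]).
#' @param positions marker positions in cM (one per marker).
#' @param window_cm matching window (default 20 cM).
#' @return object of class `qtl_detection`: list with counts
#'   `true_positives`, `false_positives`, the per-truth-entry `matches`
#'   tibble and the `unmatched` detections.
#' @export
evaluate_detection <- function(detections, truth, positions, window_cm = 20) {
  det <- detections[detections$kind %in% c("main", "epistatic"), , drop = FALSE]
  pos <- positions

  t_main <- which(truth$kind == "main")
  t_epi <- which(truth$kind == "epistatic")
  matched <- rep(FALSE, nrow(truth))
  det_match <- rep(NA_integer_, nrow(det))

  d_main <- which(det$kind == "main")
  if (length(d_main) && length(t_main)) {
    dd <- abs(outer(pos[det$locus1[d_main]], pos[truth$locus1[t_main]], "-"))
    hit <- dd <= window_cm
    for (r in seq_along(d_main)) {
      if (any(hit[r, ])) {
        # nearest truth entry within the window
        tloc <- t_main[which.min(replace(dd[r, ], !hit[r, ], Inf))]
        det_match[d_main[r]] <- tloc
        matched[tloc] <- TRUE
      }
    }
  }

  d_epi <- which(det$kind == "epistatic")
  if (length(d_epi) && length(t_epi)) {
    for (r in d_epi) {
      p1 <- pos[det$locus1[r]]; p2 <- pos[det$locus2[r]]
      best <- NA_integer_; best_tot <- Inf
      for (tt in t_epi) {
        q1 <- pos[truth$locus1[tt]]; q2 <- pos[truth$locus2[tt]]
        # order-free: try both pairings of detected to true loci
        tot1 <- max(abs(p1 - q1), abs(p2 - q2))
        tot2 <- max(abs(p1 - q2), abs(p2 - q1))
        sum1 <- abs(p1 - q1) + abs(p2 - q2)
        sum2 <- abs(p1 - q2) + abs(p2 - q1)
        if (tot1 <= window_cm && sum1 < best_tot) { best <- tt; best_tot <- sum1 }
        if (tot2 <= window_cm && sum2 < best_tot) { best <- tt; best_tot <- sum2 }
      }
      if (!is.na(best)) {
        det_match[r] <- best
        matched[best] <- TRUE
      }
    }
  }

  tp <- sum(matched)
  fp <- sum(is.na(det_match))
  matches <- tibble::tibble(
    truth_entry = which(matched),
    kind = truth$kind[matched],
    locus1 = truth$locus1[matched],
    locus2 = truth$locus2[matched])
  structure(list(true_positives = tp, false_positives = fp,
                 n_detections = nrow(det),
                 matches = matches,
                 unmatched = det[is.na(det_match), , drop = FALSE],
                 window_cm = window_cm),
            class = "qtl_detection")
}

#' @export
print.qtl_detection <- function(x, ...) {
  cat(sprintf("<qtl_detection> %d detections: %d true positive, %d false positive (window %g cM)\n",
              x$n_detections, x$true_positives, x$false_positives, x$window_cm))
  invisible(x)
}

#' Single-locus logistic regression scan
#'
#' Fits the one-marker logistic model (intercept + marker) at every marker
#' by Newton-Raphson and reports the Wald test per marker. Significance uses
#' a Bonferroni-corrected threshold `alpha / m` by default.
#'
#' @param G a [qtl_geno] object or marker matrix.
#' @param y binary phenotype.
#' @param alpha family-wise significance level (default 0.05).
#' @param correction `"bonferroni"` or `"none"`.
#' @return tibble with one row per marker: `marker`, `position`, `estimate`,
#'   `se`, `statistic`, `p_value`, `significant`, `converged`; the cutoff is
#'   stored in attribute `"cutoff"`.
#' @export
scan_single_locus <- function(G, y, alpha = 0.05,
                              correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  x <- if (inherits(G, "qtl_geno")) G$x else as.matrix(G)
  pos <- if (inherits(G, "qtl_geno")) G$pos else seq_len(ncol(x))
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("phenotype has a single class")
  m <- ncol(x)
  cutoff <- if (correction == "bonferroni") alpha / m else alpha
  est <- se <- stat <- pv <- numeric(m)
  conv <- logical(m)
  for (j in seq_len(m)) {
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, x[, j]), y,
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || fit$rank < 2) {
      est[j] <- NA_real_; se[j] <- NA_real_; stat[j] <- 0; pv[j] <- 1
      conv[j] <- FALSE
      next
    }
    conv[j] <- TRUE
    p <- fit$fitted.values
    b <- pmin(pmax(p * (1 - p), 1e-10), 0.25)
    V <- tryCatch(solve(crossprod(cbind(1, x[, j]) * sqrt(b))),
                  error = function(e) NULL)
    if (is.null(V)) {
      est[j] <- NA_real_; se[j] <- NA_real_; stat[j] <- 0; pv[j] <- 1
      conv[j] <- FALSE
      next
    }
    est[j] <- fit$coefficients[2]
    se[j] <- sqrt(V[2, 2])
    stat[j] <- est[j] / se[j]
    pv[j] <- 2 * stats::pnorm(-abs(stat[j]))
  }
  out <- tibble::tibble(marker = seq_len(m), position = pos,
                        kind = "main", locus1 = seq_len(m),
                        locus2 = NA_integer_,
                        estimate = est, se = se, statistic = stat,
                        p_value = pv, significant = pv <= cutoff,
                        converged = conv)
  attr(out, "cutoff") <- cutoff
  out
}

#' Unpenalized logistic refit of selected effects
#'
#' Refits an ordinary (maximum-likelihood) logistic regression on the
#' selected effect columns only, the post-selection step used to debias
#' shrinkage estimates. Falls back to a weakly penalized fit (ridge 1e-6)
#' with a warning under separation.
#'
#' @param X matrix of selected effect columns (no intercept), possibly with
#'   zero columns.
#' @param y binary phenotype.
#' @param keys optional tibble describing the columns (kind, locus1,
#'   locus2).
#' @return tibble of effects with `estimate`, `se`, `statistic`, `p_value`
#'   (empty when no columns were selected); intercept in attribute
#'   `"intercept"`.
#' @export
refit_unpenalized <- function(X, y, keys = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (ncol(X) > n - 2) stop("more selected columns than the refit can support")
  if (ncol(X) == 0) {
    out <- tibble::tibble(kind = character(0), locus1 = integer(0),
                          locus2 = integer(0), estimate = numeric(0),
                          se = numeric(0), statistic = numeric(0),
                          p_value = numeric(0))
    attr(out, "intercept") <- stats::qlogis(mean(y))
    return(out)
  }
  Xf <- cbind(1, X)
  mp <- tryCatch(
    map_estimate(Xf, y, alpha = rep(0, ncol(Xf))),
    ebqtl_map_error = function(e) NULL, error = function(e) NULL)
  if (is.null(mp)) {
    warning("separation in unpenalized refit; using a weak ridge penalty")
    mp <- map_estimate(Xf, y, alpha = c(0, rep(1e-6, ncol(X))))
  }
  ws <- wald_summary(mp$beta, mp$Sigma, n, ncol(X))
  if (is.null(keys)) {
    keys <- tibble::tibble(kind = rep("main", ncol(X)),
                           locus1 = seq_len(ncol(X)), locus2 = NA_integer_)
  }
  out <- dplyr::bind_cols(keys, ws[-1, ])
  attr(out, "intercept") <- ws$estimate[1]
  out
}
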