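# F2 intercross simulator: marker genotypes as two independent gamete-level
# Markov chains along a chromosome (Haldane map, no interference) and binary
# phenotypes from the sparse logistic model.

#' Simulate F2 genotypes along an evenly spaced chromosome
#'
#' Each individual's two gametes are simulated as independent Markov chains
#' over the markers: the allele at the first marker is Bernoulli(1/2) and a
#' recombination between adjacent markers occurs with the Haldane fraction
#' \eqn{r = (1 - e^{-2d/100})/2} (d in cM, no interference). The additive
#' genotype code is the allele sum mapped to {1, 0, -1}, giving Mendelian
#' 1:2:1 margins and an adjacent-marker correlation of \eqn{e^{-2d/100}}
#' (0.9048 at d = 5 cM).
#'
#' @param n number of individuals.
#' @param m number of markers.
#' @param spacing_cm inter-marker distance in cM (default 5).
#' @param pos optional explicit marker positions in cM (overrides
#'   `spacing_cm`; must be non-decreasing).
#' @return a [qtl_geno] object (`cross_type = "F2"`).
#' @export
simulate_f2_genotypes <- function(n, m, spacing_cm = 5, pos = NULL) {
  stopifnot(n >= 1, m >= 2 || is.null(pos))
  if (is.null(pos)) {
    pos <- (seq_len(m) - 1) * spacing_cm
  } else {
    m <- length(pos)
    if (is.unsorted(pos)) stop("pos must be non-decreasing")
  }
  d <- diff(pos)                      # cM
  r <- (1 - exp(-2 * d / 100)) / 2    # Haldane recombination fractions
  gam <- function() {
    a <- matrix(0L, n, m)
    a[, 1] <- stats::rbinom(n, 1, 0.5)
    if (m > 1) {
      sw <- matrix(stats::rbinom(n * (m - 1), 1, rep(r, each = n)), n, m - 1)
      a <- (a[, 1] + cbind(0L, t(apply(sw, 1, cumsum)))) %% 2L
    }
    a
  }
  g <- gam() + gam() - 1L  # -1, 0, 1
  qtl_geno(g, pos = pos, cross_type = "F2")
}

#' Simulate a binary phenotype from a sparse logistic QTL model
#'
#' Computes \eqn{p_i = 1/(1 + e^{-x_i^T\beta})} using only the effects in
#' the truth table (plus `intercept`) and draws \eqn{y_i \sim
#' Bernoulli(p_i)}.
#'
#' @param G a [qtl_geno] object.
#' @param truth a truth table: tibble with columns `kind` ("main" or
#'   "epistatic"), `locus1`, `locus2` and `beta` (see [builtin_truth()]).
#' @param intercept intercept of the logistic model (default 0).
#' @param return_prob also return the true probabilities?
#' @return integer 0/1 vector (with attribute `"prob"` when requested).
#' @export
simulate_phenotype <- function(G, truth, intercept = 0, return_prob = FALSE) {
  stopifnot(inherits(G, "qtl_geno"))
  x <- G$x
  m <- ncol(x)
  if (any(stats::na.omit(c(truth$locus1, truth$locus2)) > m)) {
    stop("truth table references loci beyond the genotype matrix")
  }
  eta <- rep(intercept, nrow(x))
  for (i in seq_len(nrow(truth))) {
    xi <- x[, truth$locus1[i]]
    if (truth$kind[i] == "epistatic") xi <- xi * x[, truth$locus2[i]]
    eta <- eta + truth$beta[i] * xi
  }
  p <- stats::plogis(eta)
  y <- stats::rbinom(length(p), 1, p)
  if (return_prob) attr(y, "prob") <- p
  y
}

#' Built-in truth tables of the two simulation designs
#'
#' `"main_only"` places 20 main-effect QTLs on a 481-marker chromosome
#' (5 cM spacing); `"main_epistatic"` places 10 main and 10 epistatic
#' effects. Effect sizes range from -1.28 to 2.19 and QTLs coincide with
#' markers.
#'
#' @param setup `"main_only"` or `"main_epistatic"`.
#' @return tibble with columns `kind`, `locus1`, `locus2`, `beta`.
#' @export
builtin_truth <- function(setup = c("main_only", "main_epistatic")) {
  setup <- match.arg(setup)
  if (setup == "main_only") {
    loci <- c(11L, 26L, 42L, 48L, 72L, 73L, 123L, 127L, 161L, 181L, 182L,
              185L, 221L, 243L, 262L, 268L, 270L, 274L, 361L, 461L)
    beta <- c(1.99, 1.81, -1.28, -0.91, 1.28, 1.81, 0.63, -0.63, 0.44, 0.99,
              2.19, 1.29, -0.75, -0.57, -1.28, 0.91, 0.57, -0.99, 0.41, 0.51)
    tibble::tibble(kind = "main", locus1 = loci, locus2 = NA_integer_,
                   beta = beta)
  } else {
    main_loci <- c(11L, 26L, 42L, 48L, 72L, 73L, 182L, 185L, 262L, 268L)
    main_beta <- c(1.99, 1.81, -1.28, -0.91, 1.28, 1.81, 2.19, 1.29, -1.28, 0.91)
    ep1 <- c(5L, 6L, 42L, 81L, 87L, 87L, 118L, 328L, 373L, 431L)
    ep2 <- c(6L, 39L, 220L, 200L, 164L, 322L, 278L, 404L, 400L, 439L)
    ep_beta <- c(1.28, 1.29, 1.99, -1.28, 1.81, 2.19, -1.28, -0.99, -0.91, 1.81)
    dplyr::bind_rows(
      tibble::tibble(kind = "main", locus1 = main_loci, locus2 = NA_integer_,
                     beta = main_beta),
      tibble::tibble(kind = "epistatic", locus1 = ep1, locus2 = ep2,
                     beta = ep_beta))
  }
}

#' Simulation designs of the two built-in setups
#'
#' Convenience wrapper bundling marker count, spacing and sample size:
#' setup 1 is m = 481, d = 5 cM, n = 500 with the 20 main effects; setup 2
#' is m = 481, d = 5 cM, n = 1000 with 10 main + 10 epistatic effects.
#'
#' @inheritParams builtin_truth
#' @return list with `m`, `spacing_cm`, `n`, `epistasis` and `truth`.
#' @export
sim_design <- function(setup = c("main_only", "main_epistatic")) {
  setup <- match.arg(setup)
  list(m = 481L, spacing_cm = 5,
       n = if (setup == "main_only") 500L else 1000L,
       epistasis = setup == "main_epistatic",
       truth = builtin_truth(setup))
}
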