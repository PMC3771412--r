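# Design-matrix expansion: intercept + additive main effects + pairwise
# epistatic (product) columns, and a column "provider" that can stream the
# epistatic expansion in blocks so the full n x k matrix (k can exceed 1e5)
# is never materialized at once.

#' Effect keys for a main + epistasis design
#'
#' Enumerates the effect columns of the multiple-QTL logistic model in the
#' fixed order: intercept, main effects 1..m, then epistatic pairs (1,2),
#' (1,3), ..., (m-1, m) (row-major over pairs j < j').
#'
#' @param m number of markers.
#' @param epistasis include pairwise product effects?
#' @param intercept include the leading intercept key (default `TRUE`)?
#' @return A tibble with columns `kind` ("intercept", "main" or "epistatic"),
#'   `locus1` and `locus2` (marker indices; `NA` where not applicable).
#' @export
effect_keys <- function(m, epistasis = FALSE, intercept = TRUE) {
  kind <- character(0); l1 <- integer(0); l2 <- integer(0)
  if (intercept) { kind <- "intercept"; l1 <- NA_integer_; l2 <- NA_integer_ }
  kind <- c(kind, rep("main", m))
  l1 <- c(l1, seq_len(m)); l2 <- c(l2, rep(NA_integer_, m))
  if (epistasis) {
    if (m < 2) stop("epistasis requires at least 2 markers")
    pr <- pair_index(m)
    kind <- c(kind, rep("epistatic", length(pr$j1)))
    l1 <- c(l1, pr$j1); l2 <- c(l2, pr$j2)
  }
  tibble::tibble(kind = kind, locus1 = l1, locus2 = l2)
}

# row-major enumeration of pairs (j, j'), j < j'
pair_index <- function(m) {
  if (m < 2) return(list(j1 = integer(0), j2 = integer(0)))
  j1 <- rep.int(seq_len(m - 1L), times = (m - 1L):1L)
  j2 <- sequence((m - 1L):1L) + j1
  list(j1 = j1, j2 = j2)
}

#' Build the dense design matrix of a multiple-QTL logistic model
#'
#' Columns are ordered intercept, main effects 1..m, then epistatic products
#' (1,2), (1,3), ..., (m-1,m). With epistasis the total column count is
#' k = 1 + m + m(m-1)/2; without it k = 1 + m. Each epistatic column is the
#' elementwise product of its two parent main-effect columns. Intended for
#' moderate m; large epistatic designs are streamed in blocks internally by
#' [eb_fit()] instead.
#'
#' @param G a [qtl_geno] object or a fully observed numeric marker matrix.
#' @param epistasis include pairwise product columns?
#' @param standardize center and scale the effect columns (never the
#'   intercept)? Off by default.
#' @return numeric matrix with an attribute `"keys"` (see [effect_keys()]).
#' @export
build_design <- function(G, epistasis = FALSE, standardize = FALSE) {
  x <- if (inherits(G, "qtl_geno")) G$x else as.matrix(G)
  if (anyNA(x)) stop("design expansion requires fully imputed genotypes")
  n <- nrow(x); m <- ncol(x)
  keys <- effect_keys(m, epistasis = epistasis)
  X <- matrix(1, n, nrow(keys))
  X[, 1L + seq_len(m)] <- x
  if (epistasis) {
    pr <- pair_index(m)
    X[, (1L + m) + seq_along(pr$j1)] <- x[, pr$j1, drop = FALSE] *
      x[, pr$j2, drop = FALSE]
  }
  if (standardize && ncol(X) > 1) {
    X[, -1] <- scale(X[, -1])
    X[is.na(X)] <- 0  # constant columns scale to NaN
  }
  attr(X, "keys") <- keys
  X
}

# ---- streaming column provider ------------------------------------------

# A provider describes the k candidate effect columns (no intercept) and can
# materialize any index subset on demand, scaled to unit Euclidean norm (the
# scale on which the shrinkage hyperparameters act; estimates are mapped
# back to the raw coding when reported). Peak memory stays O(n + m^2).
new_provider <- function(x, epistasis = FALSE, pos = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  m <- ncol(x)
  pr <- if (epistasis) pair_index(m) else list(j1 = integer(0), j2 = integer(0))
  norm_main <- sqrt(colSums(x^2))
  norm_main[norm_main == 0] <- 1
  xsq <- NULL; norm_pair <- NULL
  if (epistasis) {
    xsq <- x^2
    pn <- sqrt(crossprod(xsq))  # ||x_j * x_j'|| for every pair, m x m
    pn[pn == 0] <- 1
    norm_pair <- pn[cbind(pr$j1, pr$j2)]
  }
  structure(list(type = "geno", x = x, xsq = xsq,
                 m = m, n = nrow(x), epistasis = epistasis,
                 j1 = pr$j1, j2 = pr$j2,
                 norms = c(norm_main, norm_pair),
                 k = m + length(pr$j1), pos = pos),
            class = "eb_provider")
}

prov_ncol <- function(prov) prov$k

prov_norms <- function(prov, idx = NULL) {
  if (is.null(idx)) prov$norms else prov$norms[idx]
}

# materialize candidate columns `idx` (1..k; 1..m main, then pairs),
# unit-norm scaled
prov_cols <- function(prov, idx) {
  if (prov$type == "design") {
    return(prov$X[, idx, drop = FALSE] /
             rep(prov$norms[idx], each = prov$n))
  }
  main <- idx <= prov$m
  out <- matrix(0, prov$n, length(idx))
  if (any(main)) out[, main] <- prov$x[, idx[main], drop = FALSE]
  if (any(!main)) {
    t <- idx[!main] - prov$m
    out[, !main] <- prov$x[, prov$j1[t], drop = FALSE] *
      prov$x[, prov$j2[t], drop = FALSE]
  }
  out / rep(prov$norms[idx], each = prov$n)
}

prov_keys <- function(prov, idx) {
  if (prov$type == "design") return(prov$keys[idx, , drop = FALSE])
  main <- idx <= prov$m
  l1 <- integer(length(idx)); l2 <- rep(NA_integer_, length(idx))
  l1[main] <- idx[main]
  if (any(!main)) {
    t <- idx[!main] - prov$m
    l1[!main] <- prov$j1[t]; l2[!main] <- prov$j2[t]
  }
  tibble::tibble(kind = ifelse(main, "main", "epistatic"),
                 locus1 = l1, locus2 = l2)
}
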