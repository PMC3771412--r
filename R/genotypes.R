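#' Coded genotype matrix for an experimental cross
#'
#' Container for Cockerham-coded marker genotypes of an F2 intercross or a
#' backcross population. F2 additive coding maps the three genotype classes
#' A1A1 / A1A2 / A2A2 to 1 / 0 / -1; a backcross has two classes coded
#' -0.5 / 0.5. Missing calls are held as an explicit out-of-range sentinel
#' (`NA_real_`), never as a silent zero.
#'
#' @param x numeric matrix, individuals in rows, markers in columns.
#' @param pos numeric vector of marker positions in centi-Morgans (cM),
#'   non-decreasing within a chromosome. Defaults to marker index.
#' @param chr optional chromosome labels (one per marker).
#' @param ids marker labels; defaults to column names or `M1..Mm`.
#' @param cross_type `"F2"` or `"backcross"`.
#'
#' @return An object of class `qtl_geno`: a list with elements `x`, `pos`,
#'   `chr`, `ids` and `cross_type`.
#' @export
qtl_geno <- function(x, pos = NULL, chr = NULL, ids = NULL,
                     cross_type = c("F2", "backcross")) {
  cross_type <- match.arg(cross_type)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  m <- ncol(x)
  if (is.null(ids)) {
    ids <- colnames(x)
    if (is.null(ids)) ids <- paste0("M", seq_len(m))
  }
  if (is.null(pos)) pos <- as.numeric(seq_len(m))
  if (length(pos) != m) stop("`pos` must have one entry per marker")
  if (is.null(chr)) chr <- rep("1", m)
  chr <- as.character(chr)
  for (cc in unique(chr)) {
    p <- pos[chr == cc]
    if (is.unsorted(p)) stop("marker positions must be non-decreasing within a chromosome")
  }
  valid <- if (cross_type == "F2") c(-1, 0, 1) else c(-0.5, 0.5)
  obs <- x[!is.na(x)]
  if (length(obs) && !all(obs %in% valid)) {
    stop(sprintf("coded %s genotypes must lie in {%s}", cross_type,
                 paste(valid, collapse = ", ")))
  }
  colnames(x) <- ids
  structure(list(x = x, pos = as.numeric(pos), chr = chr, ids = ids,
                 cross_type = cross_type),
            class = "qtl_geno")
}

#' @export
print.qtl_geno <- function(x, ...) {
  nmiss <- sum(is.na(x$x))
  cat(sprintf("<qtl_geno> %s cross: %d individuals x %d markers (%s missing calls)\n",
              x$cross_type, nrow(x$x), ncol(x$x), nmiss))
  cat(sprintf("  positions: %.1f-%.1f cM on %d chromosome(s)\n",
              min(x$pos), max(x$pos), length(unique(x$chr))))
  invisible(x)
}

#' @export
dim.qtl_geno <- function(x) dim(x$x)

#' Encode raw genotype labels with the additive Cockerham coding
#'
#' Maps the three F2 genotype classes A1A1, A1A2, A2A2 to the additive codes
#' 1, 0, -1, or the two backcross classes to -0.5 and 0.5. Missing labels
#' (`NA` or empty strings) are preserved as the missing sentinel.
#'
#' @param raw character (or factor) matrix of genotype labels, individuals in
#'   rows, markers in columns.
#' @param cross_type `"F2"` or `"backcross"`.
#' @param labels genotype class labels, in the order that maps to the codes
#'   `c(1, 0, -1)` (F2) or `c(-0.5, 0.5)` (backcross).
#' @inheritParams qtl_geno
#' @return A [qtl_geno] object.
#' @export
encode_additive <- function(raw, cross_type = c("F2", "backcross"),
                            labels = NULL, pos = NULL, chr = NULL) {
  cross_type <- match.arg(cross_type)
  raw <- as.matrix(raw)
  rawc <- matrix(as.character(raw), nrow(raw), ncol(raw), dimnames = dimnames(raw))
  rawc[rawc == ""] <- NA_character_
  if (is.null(labels)) {
    labels <- if (cross_type == "F2") c("A1A1", "A1A2", "A2A2") else c("A1A1", "A1A2")
  }
  codes <- if (cross_type == "F2") c(1, 0, -1) else c(-0.5, 0.5)
  if (length(labels) != length(codes)) {
    stop(sprintf("`labels` must have %d entries for a %s cross",
                 length(codes), cross_type))
  }
  bad <- !is.na(rawc) & !(rawc %in% labels)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unknown genotype label '%s' at individual %d, marker %d",
                 rawc[w[1], w[2]], w[1], w[2]))
  }
  x <- matrix(codes[match(rawc, labels)], nrow(rawc), ncol(rawc),
              dimnames = dimnames(rawc))
  qtl_geno(x, pos = pos, chr = chr, cross_type = cross_type)
}

#' Decode additive codes back to genotype labels
#'
#' Inverse of [encode_additive()] on fully observed matrices.
#'
#' @param G a [qtl_geno] object.
#' @param labels class labels in code order (see [encode_additive()]).
#' @return character matrix of genotype labels.
#' @export
decode_additive <- function(G, labels = NULL) {
  stopifnot(inherits(G, "qtl_geno"))
  if (is.null(labels)) {
    labels <- if (G$cross_type == "F2") c("A1A1", "A1A2", "A2A2") else c("A1A1", "A1A2")
  }
  codes <- if (G$cross_type == "F2") c(1, 0, -1) else c(-0.5, 0.5)
  matrix(labels[match(G$x, codes)], nrow(G$x), ncol(G$x), dimnames = dimnames(G$x))
}

#' Impute missing genotype calls from flanking markers
#'
#' Individuals whose per-sample missing fraction exceeds `max_missing_frac`
#' are dropped. Each remaining missing call is filled with the genotype of
#' the nearest non-missing flanking marker on the same chromosome (distance
#' in cM); when the two flanks are exactly equidistant and disagree, the
#' expected coded value 0 (F2) or the class mean (backcross) is used.
#'
#' @param G a [qtl_geno] object.
#' @param max_missing_frac individuals with a larger fraction of missing
#'   marker calls are removed (default 0.1).
#' @return A fully observed [qtl_geno] object (possibly with fewer rows).
#' @export
impute_missing <- function(G, max_missing_frac = 0.1) {
  stopifnot(inherits(G, "qtl_geno"))
  x <- G$x
  if (any(colSums(!is.na(x)) == 0)) {
    stop(sprintf("marker '%s' has no observed calls; cannot impute",
                 G$ids[which(colSums(!is.na(x)) == 0)[1]]))
  }
  frac <- rowMeans(is.na(x))
  keep <- frac <= max_missing_frac
  x <- x[keep, , drop = FALSE]
  if (!any(is.na(x))) {
    return(qtl_geno(x, pos = G$pos, chr = G$chr, ids = G$ids,
                    cross_type = G$cross_type))
  }
  midfill <- if (G$cross_type == "F2") 0 else 0
  for (cc in unique(G$chr)) {
    jj <- which(G$chr == cc)
    pos <- G$pos[jj]
    for (i in which(rowSums(is.na(x[, jj, drop = FALSE])) > 0)) {
      row <- x[i, jj]
      obs <- which(!is.na(row))
      if (!length(obs)) {
        # no information on this chromosome at all: expected value
        x[i, jj] <- midfill
        next
      }
      for (j in which(is.na(row))) {
        left <- obs[obs < j]
        right <- obs[obs > j]
        dl <- if (length(left)) pos[j] - pos[max(left)] else Inf
        dr <- if (length(right)) pos[min(right)] - pos[j] else Inf
        if (dl < dr) {
          x[i, jj[j]] <- row[max(left)]
        } else if (dr < dl) {
          x[i, jj[j]] <- row[min(right)]
        } else {
          vl <- row[max(left)]; vr <- row[min(right)]
          x[i, jj[j]] <- if (vl == vr) vl else midfill
        }
      }
    }
  }
  qtl_geno(x, pos = G$pos, chr = G$chr, ids = G$ids, cross_type = G$cross_type)
}
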