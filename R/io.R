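# Tabular interchange: plain delimited text (the field has no standard
# container for coded F2 genotype matrices). Genotype CSV: first column
# sample IDs, remaining columns markers (header = marker IDs, optional
# second header row "chr:position_cM"). Phenotype CSV: sample ID + 0/1
# trait. Effects/truth/CV tables are tab-separated.

#' Write / read a coded genotype matrix as CSV
#'
#' The first column holds sample IDs; marker columns carry coded genotypes
#' (`-1/0/1` for F2, `-0.5/0.5` for backcross, `NA` for missing). A second
#' header row `#map` stores `chr:position` per marker so the map survives a
#' round trip.
#'
#' @param G a [qtl_geno] object.
#' @param path file path.
#' @return `write_genotypes()` returns `path` invisibly; `read_genotypes()`
#'   returns a [qtl_geno].
#' @export
write_genotypes <- function(G, path) {
  stopifnot(inherits(G, "qtl_geno"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", G$ids), collapse = ","), con)
  writeLines(paste(c("#map", paste0(G$chr, ":", G$pos)), collapse = ","), con)
  ids <- rownames(G$x)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(G$x)))
  utils::write.table(data.frame(id = ids, G$x, check.names = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @param cross_type cross type of the file being read.
#' @export
read_genotypes <- function(path, cross_type = c("F2", "backcross")) {
  cross_type <- match.arg(cross_type)
  lines <- readLines(path, n = 2)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  has_map <- length(lines) > 1 && startsWith(lines[2], "#map")
  pos <- NULL; chr <- NULL
  if (has_map) {
    mp <- strsplit(lines[2], ",", fixed = TRUE)[[1]][-1]
    parts <- strsplit(mp, ":", fixed = TRUE)
    chr <- vapply(parts, `[`, "", 1)
    pos <- as.numeric(vapply(parts, `[`, "", 2))
  }
  df <- utils::read.csv(path, skip = if (has_map) 2 else 1, header = FALSE,
                        check.names = FALSE)
  ids <- df[[1]]
  x <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(x) <- "double"
  colnames(x) <- header[-1]
  rownames(x) <- ids
  qtl_geno(x, pos = pos, chr = chr, ids = header[-1], cross_type = cross_type)
}

#' Write / read a binary phenotype CSV (sample ID + 0/1 value)
#'
#' @param y 0/1 vector; names (or `ids`) become sample IDs.
#' @param path file path.
#' @param ids optional sample IDs.
#' @return `read_phenotypes()` returns a named 0/1 vector.
#' @export
write_phenotypes <- function(y, path, ids = NULL) {
  if (is.null(ids)) ids <- names(y)
  if (is.null(ids)) ids <- paste0("S", seq_along(y))
  utils::write.csv(data.frame(id = ids, phenotype = as.numeric(y)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path)
  y <- df[[2]]
  if (!all(y %in% c(0, 1))) {
    bad <- y[!(y %in% c(0, 1))][1]
    stop(sprintf("phenotype values must be 0/1; found '%s'", bad))
  }
  stats::setNames(as.numeric(y), as.character(df[[1]]))
}

#' Write an effects table (or truth table) as TSV
#'
#' @param effects tibble of effects (e.g. `tidy(fit)` or a truth table).
#' @param path file path.
#' @export
write_effects <- function(effects, path) {
  utils::write.table(as.data.frame(effects), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}
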