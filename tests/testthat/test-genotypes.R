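test_that("additive coding maps F2 and backcross classes to Cockerham codes", {
  raw <- matrix(c("A1A1", "A1A2", "A2A2"), 3, 1)
  G <- encode_additive(raw, "F2")
  expect_equal(as.vector(G$x), c(1, 0, -1))

  raw_bc <- matrix(c("A1A1", "A1A2", "A1A2", "A1A1"), 2, 2)
  Gbc <- encode_additive(raw_bc, "backcross")
  expect_true(all(Gbc$x %in% c(-0.5, 0.5)))
  expect_equal(sort(unique(as.vector(Gbc$x))), c(-0.5, 0.5))

  het <- matrix("A1A2", 5, 2)
  expect_true(all(encode_additive(het, "F2")$x == 0))
})

test_that("unknown labels are rejected with the offending cell named", {
  raw <- matrix(c("A1A1", "XX", "A2A2", "A1A2"), 2, 2)
  expect_error(encode_additive(raw, "F2"), "XX.*individual 2, marker 1")
})

test_that("encode then decode is the identity on genotype classes", {
  set.seed(1)
  raw <- matrix(sample(c("A1A1", "A1A2", "A2A2"), 60, replace = TRUE), 10, 6)
  expect_equal(decode_additive(encode_additive(raw, "F2")), raw,
               ignore_attr = TRUE)
})

test_that("missing calls survive encoding as NA, never as zero", {
  raw <- matrix(c("A1A1", NA, "A2A2"), 3, 1)
  G <- encode_additive(raw, "F2")
  expect_true(is.na(G$x[2, 1]))
  expect_equal(G$x[c(1, 3), 1], c(1, -1), ignore_attr = TRUE)
})

test_that("imputation fills from flanking markers and drops bad samples", {
  # missing call flanked by identical genotypes -> that genotype
  x <- rbind(c(1, NA, 1, 0, -1),
             c(0, 0, 0, 0, 0))
  G <- qtl_geno(x, pos = c(0, 5, 10, 15, 20))
  Gi <- impute_missing(G, max_missing_frac = 0.5)
  expect_equal(unname(Gi$x[1, 2]), 1)

  # nearest flank wins when distances differ
  xn <- rbind(c(1, NA, -1), c(0, 0, 0))
  Gn <- impute_missing(qtl_geno(xn, pos = c(0, 2, 10)), max_missing_frac = 0.5)
  expect_equal(unname(Gn$x[1, 2]), 1)

  # equidistant disagreeing flanks -> expected value 0
  x2 <- rbind(c(1, NA, -1), c(1, 1, 1))
  Gi2 <- impute_missing(qtl_geno(x2, pos = c(0, 5, 10)), max_missing_frac = 0.5)
  expect_equal(unname(Gi2$x[1, 2]), 0)

  # sample with 11% missing at threshold 10% is removed
  x3 <- matrix(0, 4, 100)
  x3[1, 1:11] <- NA      # 11% missing
  x3[2, 1] <- NA         # 1% missing
  Gi3 <- impute_missing(qtl_geno(x3), max_missing_frac = 0.1)
  expect_equal(nrow(Gi3$x), 3)
  expect_false(anyNA(Gi3$x))

  # complete matrix is returned unchanged
  x4 <- matrix(sample(c(-1, 0, 1), 50, TRUE), 10, 5)
  expect_equal(impute_missing(qtl_geno(x4))$x, qtl_geno(x4)$x)

  # a marker with no observed calls cannot be imputed
  x5 <- matrix(0, 3, 4); x5[, 2] <- NA
  expect_error(impute_missing(qtl_geno(x5)), "no observed calls")
})

test_that("design size follows 1 + m + m(m-1)/2 and column order is fixed", {
  for (m in 1:10) {
    keys <- effect_keys(m, epistasis = m >= 2)
    expect_equal(nrow(keys), 1 + m + if (m >= 2) m * (m - 1) / 2 else 0)
  }
  # the 481-marker epistatic design of the simulation study
  expect_equal(nrow(effect_keys(481, epistasis = TRUE)), 115922)

  keys <- effect_keys(3, epistasis = TRUE)
  expect_equal(keys$kind, c("intercept", "main", "main", "main",
                            "epistatic", "epistatic", "epistatic"))
  expect_equal(keys$locus1[5:7], c(1L, 1L, 2L))
  expect_equal(keys$locus2[5:7], c(2L, 3L, 3L))
})

test_that("build_design expands products and keys round-trip to columns", {
  x <- cbind(c(1, 0, -1), c(1, 1, -1))
  X <- build_design(qtl_geno(x, pos = c(0, 5)), epistasis = TRUE)
  expect_equal(ncol(X), 4)  # intercept, 2 main, 1 product
  expect_equal(X[, 4], c(1, 0, 1))

  set.seed(2)
  g <- matrix(sample(c(-1, 0, 1), 8 * 5, TRUE), 8, 5)
  X2 <- build_design(g, epistasis = TRUE)
  keys <- attr(X2, "keys")
  for (r in seq_len(nrow(keys))) {
    expected <- switch(keys$kind[r],
                       intercept = rep(1, 8),
                       main = g[, keys$locus1[r]],
                       epistatic = g[, keys$locus1[r]] * g[, keys$locus2[r]])
    expect_identical(X2[, r], expected)
  }
  expect_identical(build_design(g, epistasis = TRUE), X2)  # deterministic

  expect_error(build_design(matrix(c(1, 0, -1), 3, 1), epistasis = TRUE),
               "at least 2")
  expect_error(build_design(qtl_geno(matrix(c(1, NA, 0), 3, 1))),
               "fully imputed")
})
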