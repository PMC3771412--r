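test_that("adjacent-marker correlation follows the Haldane map", {
  set.seed(101)
  G <- simulate_f2_genotypes(n = 5000, m = 12, spacing_cm = 5)
  R <- exp(-2 * 5 / 100)  # 0.9048
  cors <- vapply(1:11, function(j) cor(G$x[, j], G$x[, j + 1]), numeric(1))
  # the 11 interval correlations are nearly independent (distinct
  # recombination draws): their mean estimates R to ~0.001
  expect_lt(abs(mean(cors) - R), 0.01)
  expect_true(all(abs(cors - R) < 0.02))
})

test_that("lag-l correlation composes as exp(-2 l d) (Markov property)", {
  set.seed(102)
  d <- 10
  G <- simulate_f2_genotypes(n = 5000, m = 11, spacing_cm = d)
  for (lag in c(1, 2, 5)) {
    target <- exp(-2 * lag * d / 100)
    cors <- vapply(seq_len(11 - lag),
                   function(j) cor(G$x[, j], G$x[, j + lag]), numeric(1))
    expect_lt(abs(mean(cors) - target), 0.02)
    expect_true(all(abs(cors - target) < 0.045))
  }
})

test_that("zero map distance gives identical adjacent columns", {
  set.seed(103)
  G <- simulate_f2_genotypes(n = 200, m = 5, spacing_cm = 0)
  for (j in 2:5) expect_identical(G$x[, j], G$x[, 1])
})

test_that("marginal genotype frequencies are Mendelian 1:2:1", {
  set.seed(104)
  G <- simulate_f2_genotypes(n = 5000, m = 4, spacing_cm = 50)
  counts <- table(factor(G$x[, 2], levels = c(-1, 0, 1)))
  p <- stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
  expect_gt(p, 0.001)
})

test_that("phenotype probabilities follow the logistic model exactly", {
  # empty truth: p = 0.5 everywhere
  set.seed(105)
  G <- simulate_f2_genotypes(n = 2000, m = 3, spacing_cm = 10)
  empty <- tibble::tibble(kind = character(0), locus1 = integer(0),
                          locus2 = integer(0), beta = numeric(0))
  y0 <- simulate_phenotype(G, empty, return_prob = TRUE)
  expect_equal(attr(y0, "prob"), rep(0.5, 2000))
  expect_lt(abs(mean(y0) - 0.5), 3 * 0.5 / sqrt(2000))

  # saturating effect: y = 1 whenever x = 1
  truth_sat <- tibble::tibble(kind = "main", locus1 = 1L,
                              locus2 = NA_integer_, beta = 20)
  ys <- simulate_phenotype(G, truth_sat)
  expect_true(all(ys[G$x[, 1] == 1] == 1))
  expect_true(all(ys[G$x[, 1] == -1] == 0))

  # hand-computed 3-sample instance, main + epistatic
  Gh <- qtl_geno(rbind(c(1, 0, -1), c(-1, 1, 1), c(0, -1, 1)),
                 pos = c(0, 5, 10))
  th <- tibble::tibble(kind = c("main", "epistatic"),
                       locus1 = c(2L, 1L), locus2 = c(NA_integer_, 3L),
                       beta = c(1.5, -2))
  yh <- simulate_phenotype(Gh, th, return_prob = TRUE)
  eta <- c(1.5 * 0 - 2 * (1 * -1), 1.5 * 1 - 2 * (-1 * 1), 1.5 * -1 - 2 * 0)
  expect_equal(attr(yh, "prob"), stats::plogis(eta))

  # conditional rate given genotype class matches the model (one QTL)
  truth1 <- tibble::tibble(kind = "main", locus1 = 2L, locus2 = NA_integer_,
                           beta = 1.2)
  y1 <- simulate_phenotype(G, truth1)
  for (gval in c(-1, 0, 1)) {
    sel <- G$x[, 2] == gval
    phat <- mean(y1[sel])
    ptrue <- stats::plogis(1.2 * gval)
    expect_lt(abs(phat - ptrue), 4 * sqrt(ptrue * (1 - ptrue) / sum(sel)))
  }
})

test_that("built-in truth tables carry the published designs", {
  t1 <- builtin_truth("main_only")
  expect_equal(nrow(t1), 20)
  expect_true(all(t1$kind == "main"))
  expect_equal(t1$beta[t1$locus1 == 42], -1.28)
  expect_equal(t1$beta[t1$locus1 == 11], 1.99)
  expect_equal(t1$beta[t1$locus1 == 182], 2.19)
  expect_equal(range(t1$beta), c(-1.28, 2.19))

  t2 <- builtin_truth("main_epistatic")
  expect_equal(sum(t2$kind == "main"), 10)
  expect_equal(sum(t2$kind == "epistatic"), 10)
  expect_equal(t2$beta[t2$locus1 == 87 & t2$locus2 == 322], 2.19)
  expect_true(all(t2$locus1[t2$kind == "epistatic"] <
                    t2$locus2[t2$kind == "epistatic"]))
  expect_error(builtin_truth("nope"))
})

test_that("detection matching honors the 20 cM window and merges duplicates", {
  truth <- tibble::tibble(kind = "main", locus1 = c(10L, 40L),
                          locus2 = NA_integer_, beta = c(1, -1))
  pos <- (0:59) * 5  # 60 markers at 5 cM
  det1 <- tibble::tibble(kind = "main", locus1 = 10L, locus2 = NA_integer_)
  r1 <- evaluate_detection(det1, truth, pos)
  expect_equal(c(r1$true_positives, r1$false_positives), c(1, 0))

  # 25 cM away -> false positive
  det2 <- tibble::tibble(kind = "main", locus1 = 15L, locus2 = NA_integer_)
  r2 <- evaluate_detection(det2, truth, pos)
  expect_equal(c(r2$true_positives, r2$false_positives), c(0, 1))

  # two detections 5 and 10 cM from the same QTL merge into one TP
  det3 <- tibble::tibble(kind = "main", locus1 = c(11L, 12L),
                         locus2 = NA_integer_)
  r3 <- evaluate_detection(det3, truth, pos)
  expect_equal(c(r3$true_positives, r3$false_positives), c(1, 0))
})

test_that("detection evaluation is order-invariant and pair-symmetric", {
  truth <- tibble::tibble(kind = c("main", "epistatic"),
                          locus1 = c(10L, 20L), locus2 = c(NA_integer_, 35L),
                          beta = c(1, 2))
  pos <- (0:49) * 5
  det <- tibble::tibble(kind = c("epistatic", "main", "main"),
                        locus1 = c(36L, 11L, 48L), locus2 = c(21L, NA, NA))
  r <- evaluate_detection(det, truth, pos)
  expect_equal(c(r$true_positives, r$false_positives), c(2, 1))
  # permuting the detection list changes nothing
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    rp <- evaluate_detection(det[perm, ], truth, pos)
    expect_equal(rp$true_positives, r$true_positives)
    expect_equal(rp$false_positives, r$false_positives)
  }
  # epistatic pair outside the window on one locus is a false positive
  det_far <- tibble::tibble(kind = "epistatic", locus1 = 20L, locus2 = 45L)
  rf <- evaluate_detection(det_far, truth, pos)
  expect_equal(c(rf$true_positives, rf$false_positives), c(0, 1))
})
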