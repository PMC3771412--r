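test_that("initialization picks the best-correlated column and inverts its LS slope", {
  # orthogonal two-column toy: column 1 proportional to (y - p0)
  y <- rep(c(1, 0), each = 10)
  x1 <- y - mean(y)
  x2 <- rep(c(1, -1), 10)   # orthogonal to x1
  init <- eb_initialize(cbind(x1, x2), y)
  expect_equal(init$idx, 1L)
  expect_equal(init$p0, 0.5)

  # alpha = 1/beta^2 with beta from least squares on the centered
  # unit-norm-scaled column
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  y2 <- rbinom(20, 1, 0.5); y2[1] <- 1; y2[2] <- 0
  init2 <- eb_initialize(X, y2)
  xj <- X[, init2$idx] / sqrt(sum(X[, init2$idx]^2))
  xt <- xj - mean(xj)
  expect_equal(mean(xt), 0)
  beta_ls <- sum(xt * (y2 - mean(y2))) / sum(xt^2)
  expect_equal(init2$alpha, 1 / beta_ls^2)

  expect_error(eb_initialize(X, rep(1, 20)), "constant")
})

test_that("no candidate is added when every q^2 - s is under the threshold", {
  set.seed(8)
  n <- 30; k <- 6
  X <- unit_norm(matrix(rnorm(n * k), n, k))
  B <- rep(0.25, n)
  yp <- rnorm(n, 0, 0.1)   # essentially pure small noise
  m0 <- eb_active(X[, integer(0), drop = FALSE], numeric(0), B, yp,
                  idx = integer(0))
  res <- eb_linear_pass(m0, X, prior_ne(50))
  expect_length(res$alpha, 0)
  expect_identical(attr(res, "n_add"), 0L)
})

test_that("a single strong simulated effect is the first column added", {
  set.seed(9)
  n <- 60; k <- 8
  X <- unit_norm(matrix(rnorm(n * k), n, k))
  yp <- 10 * X[, 4] + rnorm(n, 0, 0.5)
  B <- rep(0.25, n)
  m0 <- eb_active(X[, integer(0), drop = FALSE], numeric(0), B, yp,
                  idx = integer(0))
  res <- eb_linear_pass(m0, X, prior_ne(0.05))
  expect_match(attr(res, "events")[1], "^add 4 ")
  expect_true(4L %in% res$idx)
})

test_that("the marginal posterior never decreases across accepted actions", {
  for (seed in 1:4) {
    set.seed(seed * 13)
    n <- 40; k <- 20
    X <- unit_norm(matrix(rnorm(n * k), n, k))
    B <- runif(n, 0.05, 0.25)
    yp <- rnorm(n, 0, 1.5) + 8 * X[, 3] - 6 * X[, 11] + 5 * X[, 17]
    m0 <- eb_active(X[, integer(0), drop = FALSE], numeric(0), B, yp,
                    idx = integer(0))
    prior <- if (seed %% 2) prior_ne(0.1) else prior_neg(0.05, 2)
    res <- eb_linear_pass(m0, X, prior)
    gains <- attr(res, "gains")
    gains <- gains[!is.na(gains)]
    expect_true(all(gains > 0))
    # the exact per-action gains must add up to the dense objective change
    L0 <- ebqtl:::eb_objective_dense(X[, integer(0), drop = FALSE],
                                     numeric(0), B, yp, prior)
    L1 <- ebqtl:::eb_objective_dense(res$X, res$alpha, B, yp, prior)
    expect_equal(L1 - L0, sum(gains), tolerance = 1e-6)
    expect_gte(L1 - L0, 0)
  }
})

test_that("identical inputs produce identical fits (determinism)", {
  set.seed(21)
  G <- simulate_f2_genotypes(n = 120, m = 25, spacing_cm = 10)
  truth <- tibble::tibble(kind = "main", locus1 = c(5L, 18L),
                          locus2 = NA_integer_, beta = c(1.6, -1.6))
  y <- simulate_phenotype(G, truth)
  f1 <- eb_fit(G, y, prior_neg(0.01, 6))
  f2 <- eb_fit(G, y, prior_neg(0.01, 6))
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$log, f2$log)
})

test_that("null data yields at most a couple of nominally significant effects", {
  for (seed in 1:2) {
    set.seed(seed * 100)
    G <- simulate_f2_genotypes(n = 500, m = 50, spacing_cm = 5)
    y <- stats::rbinom(500, 1, 0.5)
    fit <- eb_fit(G, y, prior_neg(0.01, 6))
    expect_lte(sum(fit$effects$significant), 2)
  }
})

test_that("a strong single QTL is recovered at or near its marker", {
  set.seed(31)
  G <- simulate_f2_genotypes(n = 500, m = 50, spacing_cm = 5)
  truth <- tibble::tibble(kind = "main", locus1 = 25L, locus2 = NA_integer_,
                          beta = 2)
  y <- simulate_phenotype(G, truth)
  fit <- eb_fit(G, y, prior_neg(0.01, 6))
  sig <- tidy(fit, significant_only = TRUE)
  expect_gt(nrow(sig), 0)
  expect_true(any(abs(G$pos[sig$locus1] - G$pos[25]) <= 20))
})

test_that("five well-separated moderate effects are recovered in most replicates", {
  truth <- tibble::tibble(kind = "main",
                          locus1 = c(10L, 30L, 50L, 70L, 90L),
                          locus2 = NA_integer_,
                          beta = c(1.5, -1.6, 1.8, -1.5, 1.7))
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    G <- simulate_f2_genotypes(n = 500, m = 100, spacing_cm = 10)
    y <- simulate_phenotype(G, truth)
    fit <- eb_fit(G, y, prior_neg(0.01, 6))
    det <- evaluate_detection(tidy(fit, TRUE), truth, G$pos, window_cm = 20)
    if (det$true_positives == 5) hits <- hits + 1L
  }
  expect_gte(hits, 8)
})

test_that("Wald summaries follow t = beta/sqrt(Sigma_ii)", {
  ws <- wald_summary(c(0.1, 2), diag(c(0.04, 4)), n = 50, k_m = 1)
  expect_equal(ws$statistic[2], 1)         # 2 / sqrt(4)
  expect_equal(ws$se, c(0.2, 2))
  ws0 <- wald_summary(0, matrix(1), n = 50, k_m = 0)
  expect_equal(ws0$statistic, 0)
  expect_equal(ws0$p_value, 1)
  # p monotone decreasing in |t|
  tgrid <- seq(0.2, 5, length.out = 10)
  ps <- wald_summary(tgrid, diag(rep(1, 10)), n = 30, k_m = 9)$p_value
  expect_true(all(diff(ps) < 0))
  # df = 1 compatibility option is more conservative
  w_res <- wald_summary(2, matrix(1), n = 100, k_m = 1, df = "residual")
  w_one <- wald_summary(2, matrix(1), n = 100, k_m = 1, df = "one")
  expect_gt(w_one$p_value, w_res$p_value)
})

test_that("uniform prior is the lambda -> 0 limit of NE in a whole fit", {
  set.seed(77)
  G <- simulate_f2_genotypes(n = 200, m = 20, spacing_cm = 20)
  truth <- tibble::tibble(kind = "main", locus1 = c(4L, 15L),
                          locus2 = NA_integer_, beta = c(1.8, -1.8))
  y <- simulate_phenotype(G, truth)
  f_unif <- eb_fit(G, y, prior_uniform())
  f_ne0 <- eb_fit(G, y, prior_ne(0))
  expect_equal(tidy(f_unif)$estimate, tidy(f_ne0)$estimate, tolerance = 1e-8)
})
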