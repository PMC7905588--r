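test_that("one-variable blocks give the absolute Pearson correlation", {
  set.seed(31)
  x <- rnorm(80)
  y <- -0.6 * x + rnorm(80)
  fit <- fit_cca(cbind(x = x), cbind(y = y))
  expect_equal(fit$cor, abs(cor(x, y)), tolerance = 1e-12)
  # loadings of 1-D blocks are +/- 1
  expect_equal(abs(unname(fit$x_loadings[1, 1])), 1, tolerance = 1e-12)
  expect_equal(abs(unname(fit$y_loadings[1, 1])), 1, tolerance = 1e-12)
})

test_that("an invertible linear transform of X yields all canonical correlations 1", {
  set.seed(32)
  X <- matrix(rnorm(200 * 3), 200, 3)
  M <- matrix(c(2, 1, 0, 0, 1, 1, 1, 0, 3), 3, 3)
  fit <- fit_cca(X, X %*% M)
  expect_equal(fit$cor, rep(1, 3), tolerance = 1e-8)
})

test_that("canonical correlations are invariant under affine transforms of either block", {
  set.seed(33)
  n <- 150
  Z <- rnorm(n)
  X <- sapply(1:4, function(j) 0.5 * Z + rnorm(n))
  Y <- sapply(1:3, function(j) 0.4 * Z + rnorm(n))
  base <- fit_cca(X, Y)$cor
  Ax <- matrix(rnorm(16), 4, 4); while (abs(det(Ax)) < 0.1) Ax <- matrix(rnorm(16), 4, 4)
  Ay <- matrix(rnorm(9), 3, 3); while (abs(det(Ay)) < 0.1) Ay <- matrix(rnorm(9), 3, 3)
  tx <- fit_cca(sweep(X %*% Ax, 2, c(5, -2, 0, 100), "+"), Y)$cor
  ty <- fit_cca(X, sweep(Y %*% Ay, 2, c(-1, 3, 9), "+"))$cor
  expect_equal(tx, base, tolerance = 1e-8)
  expect_equal(ty, base, tolerance = 1e-8)
})

test_that("implementation agrees with independent oracles on random blocks", {
  set.seed(34)
  for (rep in 1:10) {
    n <- 60; p <- sample(2:5, 1); q <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p)
    Y <- matrix(rnorm(n * q), n, q)
    fit <- fit_cca(X, Y)
    # generalized-eigenvalue brute force
    expect_equal(fit$cor, oracle_cca_cor(X, Y), tolerance = 1e-10)
    # base R's cancor as a second, library cross-check
    cc <- cancor(scale(X), scale(Y))
    expect_equal(fit$cor, cc$cor, tolerance = 1e-8)
  }
})

test_that("first canonical correlation dominates every single-pair correlation", {
  set.seed(35)
  X <- matrix(rnorm(120 * 4), 120, 4)
  Y <- 0.3 * X[, c(1, 2, 3)] + matrix(rnorm(120 * 3), 120, 3)
  fit <- fit_cca(X, Y)
  expect_gte(fit$cor[1], max(abs(cor(X, Y))) - 1e-12)
})

test_that("variates have unit variance and the sign convention makes the top x-loading positive", {
  set.seed(36)
  X <- matrix(rnorm(100 * 3), 100, 3)
  Y <- 0.5 * X + matrix(rnorm(100 * 3), 100, 3)
  fit <- fit_cca(X, Y)
  U <- scale(X) %*% fit$x_coef
  expect_equal(apply(U, 2, var), rep(1, 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (k in 1:3) {
    expect_gt(fit$x_loadings[which.max(abs(fit$x_loadings[, k])), k], 0)
  }
  # the correlation between paired variates stays positive after sign fixing
  V <- scale(Y) %*% fit$y_coef
  expect_equal(diag(cor(U, V)), fit$cor, tolerance = 1e-10)
})

test_that("structure loadings are own-block correlations, sorted by magnitude", {
  set.seed(37)
  Z <- rnorm(400)
  X <- cbind(a = Z + 0.2 * rnorm(400), b = rnorm(400), c = -Z + 0.3 * rnorm(400))
  Y <- cbind(d = Z + 0.25 * rnorm(400), e = rnorm(400))
  fit <- fit_cca(X, Y)
  sl <- structure_loadings(fit)
  expect_equal(sl$loading, sl$loading[order(-abs(sl$loading))])
  expect_equal(sl$rank, seq_len(nrow(sl)))
  # the noise variable has loading near 0 (|r| < 3/sqrt(n))
  expect_lt(abs(sl$loading[sl$variable == "b"]), 3 / sqrt(400))
  expect_lt(abs(sl$loading[sl$variable == "e"]), 3 / sqrt(400))
  # recomputing from the data matches the stored loadings
  sl2 <- structure_loadings(fit, X, Y)
  expect_equal(sl2$loading, sl$loading, tolerance = 1e-12)
})

test_that("fit validates its preconditions", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_cca(X, matrix(rnorm(18), 9, 2)), "same number of rows")
  expect_error(fit_cca(matrix(rnorm(12), 6, 2), matrix(rnorm(30), 6, 5)),
               "n > p \\+ q")
  Xc <- cbind(X, 1)
  expect_error(fit_cca(Xc, matrix(rnorm(20), 10, 2)), "constant")
  Xd <- cbind(X, X[, 1])                 # exactly collinear
  expect_error(fit_cca(Xd, matrix(rnorm(20), 10, 2)), "rank deficient")
})

test_that("Bartlett test is sequential over dimensions and detects planted signal", {
  set.seed(38)
  n <- 250
  u <- rnorm(n)
  X <- sapply(1:3, function(j) 0.7 * u + rnorm(n))
  Y <- sapply(1:3, function(j) 0.7 * u + rnorm(n))
  fit <- fit_cca(X, Y)
  bt <- cca_significance(fit)
  expect_equal(nrow(bt), 3L)
  expect_lt(bt$p_value[1], 0.05)      # strong first dimension
  expect_gt(bt$p_value[2], 0.05)      # nothing beyond it
  expect_equal(bt$df, c(9, 4, 1))
})

test_that("planted rho = 0.5 at n = 250 is declared significant in nearly all replicates", {
  set.seed(39)
  hits <- 0L
  reps <- 50L
  for (r in seq_len(reps)) {
    u <- rnorm(250); v <- 0.5 * u + sqrt(0.75) * rnorm(250)
    X <- sapply(1:3, function(j) u + 0.5 * rnorm(250))
    Y <- sapply(1:3, function(j) v + 0.5 * rnorm(250))
    fit <- fit_cca(X, Y)
    if (fit$p_value[1] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})

test_that("permutation and Bartlett tests agree on the null in most replicates", {
  set.seed(40)
  agree <- 0L
  reps <- 30L
  for (r in seq_len(reps)) {
    X <- matrix(rnorm(120 * 3), 120, 3)
    Y <- matrix(rnorm(120 * 3), 120, 3)
    fit <- fit_cca(X, Y)
    pb <- fit$p_value[1]
    pp <- cca_significance(fit, "permutation", X = X, Y = Y,
                           n_perm = 99)$p_value
    if ((pb < 0.05) == (pp < 0.05)) agree <- agree + 1L
  }
  expect_gte(agree / reps, 0.9)
})
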