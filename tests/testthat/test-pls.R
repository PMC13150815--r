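test_that("one latent variable captures a rank-one signal exactly", {
  set.seed(1)
  t_ <- rnorm(30); p_ <- rnorm(20)
  X <- outer(t_, p_)
  y <- 2 + 3 * t_ * sum(p_^2)
  fit <- fit_pls(X, y, 1)
  expect_equal(r2(predict(fit, X), y), 1, tolerance = 1e-9)
})

test_that("full-rank PLS equals least squares (pseudoinverse oracle)", {
  set.seed(2)
  X <- matrix(rnorm(20 * 8), 20, 8)
  y <- rnorm(20)
  fit <- fit_pls(X, y, 8)
  Xc <- scale(X, scale = FALSE)
  beta_ls <- qr.solve(Xc, y - mean(y))
  pred_ls <- drop(Xc %*% beta_ls) + mean(y)
  expect_equal(predict(fit, X), pred_ls, tolerance = 1e-6)
})

test_that("NIPALS scores are mutually orthogonal and beta reproduces them", {
  set.seed(3)
  X <- matrix(rnorm(40 * 15), 40, 15)
  y <- rnorm(40)
  fit <- fit_pls(X, y, 6)
  G <- crossprod(fit$scores)
  expect_lte(max(abs(G[upper.tri(G)])), 1e-8)
  # the regression-vector form equals the score-space prediction T q
  Xc <- sweep(X, 2, fit$x_mean, `-`)
  expect_equal(drop(Xc %*% fit$beta[, 6]), drop(fit$scores %*% fit$q),
               tolerance = 1e-8)
  expect_error(fit_pls(X, rep(1, 40), 2), "zero variance")
  expect_error(fit_pls(X, y, 40), "n_lv")
})

test_that("a permuted response yields no cross-validated predictivity", {
  set.seed(4)
  X <- matrix(rnorm(200 * 50), 200, 50)
  y <- X[, 1] + rnorm(200, 0, 0.1)
  y_perm <- sample(y)
  cv <- venetian_cv(X, y_perm, max_lv = 10)
  r2cv <- 1 - cv$rmsecv^2 / mean((y_perm - mean(y_perm))^2)
  expect_lte(max(r2cv), 0.1)
})

test_that("venetian blinds interleave systematically and match a brute-force oracle", {
  set.seed(5)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- rnorm(20)
  cv <- venetian_cv(X, y, max_lv = 3, k = 10)
  expect_identical(cv$folds[1], cv$folds[11])
  expect_true(all(table(cv$folds) == 2))

  # explicit refit per (fold, lv)
  for (lv in 1:3) {
    preds <- numeric(20)
    for (fold in 1:10) {
      test <- cv$folds == fold
      fit <- fit_pls(X[!test, ], y[!test], lv)
      preds[test] <- predict(fit, X[test, , drop = FALSE])
    }
    expect_equal(sqrt(mean((preds - y)^2)), cv$rmsecv[lv], tolerance = 1e-10)
  }
  expect_error(venetian_cv(X[1:5, ], y[1:5], k = 10), "more folds")
})

test_that("cross-validated predictions never see the held-out sample", {
  set.seed(6)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rnorm(30)
  cv <- venetian_cv(X, y, max_lv = 3, k = 10)
  y_poison <- y; y_poison[3] <- 1e6
  cv_poison <- venetian_cv(X, y_poison, max_lv = 3, k = 10)
  expect_equal(cv_poison$predictions[3, ], cv$predictions[3, ],
               tolerance = 1e-10)
})

test_that("noiseless linear data cross-validates to near-zero error", {
  set.seed(7)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- drop(X %*% rnorm(10))
  cv <- venetian_cv(X, y, max_lv = 10)
  expect_lte(min(cv$rmsecv), 1e-8 * sd(y))
})

test_that("LV selection rules follow their stated arithmetic", {
  expect_identical(select_lv_min(c(3, 1, 2)), 2L)
  expect_identical(select_lv_min(c(1, 1, 1)), 1L)
  expect_identical(select_lv_min(c(5, 4, 3, 2, 1)), 5L)

  r <- c(10, 5, 4.8, 4.7, 4.65, 4.6)
  expect_identical(select_lv_incremental(r), 5L)
  expect_identical(select_lv_incremental(r, floor = 0), 2L)
  expect_identical(select_lv_incremental(c(1, 2, 3, 4)), 1L)
  halving <- 100 * 0.5^(0:7)
  expect_identical(select_lv_incremental(halving), 8L)
  expect_identical(select_lv_incremental(r, floor_mode = "min_lv"), 5L)
})

test_that("VIP scores obey the normalization identity and rank informative variables", {
  set.seed(8)
  X <- matrix(rnorm(50 * 12), 50, 12)
  y <- rnorm(50)
  fit <- fit_pls(X, y, 4)
  v <- vip_scores(fit)
  expect_equal(mean(v^2), 1, tolerance = 1e-9)

  # one informative variable, noiseless
  X2 <- matrix(rnorm(50 * 10), 50, 10)
  y2 <- 5 * X2[, 4]
  v2 <- vip_scores(fit_pls(X2, y2, 1))
  expect_identical(which.max(v2), 4L)

  # duplicated informative columns share the same score
  X3 <- cbind(X2, X2[, 4])
  v3 <- vip_scores(fit_pls(X3, y2, 1))
  expect_equal(v3[4], v3[11], tolerance = 1e-9)
})

test_that("integration restores band shape from derivative-scale vectors", {
  expect_equal(integrated_vector(rep(2, 5)), c(2, 4, 6, 8, 10))
  ax <- small_axis()
  x <- as.numeric(ax)
  y <- exp(-((x - 1400)^2) / 5000)
  d <- sg_first_derivative(y, ax)
  rec <- integrated_vector(d, step = 2)
  interior <- seq(10, length(x) - 10)
  expect_lt(max(abs((rec[interior] - rec[10]) - (y[interior] - y[10]))), 0.02)
})

test_that("orthogonalized loadings rotate without changing the span", {
  set.seed(9)
  X <- matrix(rnorm(40 * 12), 40, 12)
  y <- drop(X %*% c(rep(1, 3), rep(0, 9))) + rnorm(40, 0, 0.1)
  fit <- fit_pls(X, y, 4)
  L <- orthogonalized_loadings(fit)
  expect_identical(dim(L), dim(fit$P))
  # span preserved: principal angles between the two column spaces ~ 0
  q1 <- qr.Q(qr(fit$P)); q2 <- qr.Q(qr(L))
  expect_equal(svd(crossprod(q1, q2))$d, rep(1, 4), tolerance = 1e-8)
  # first direction is the in-span projection of the regression vector
  beta <- regression_vector(fit)
  proj <- fit$P %*% solve(crossprod(fit$P), crossprod(fit$P, beta))
  cosang <- sum(L[, 1] * proj) / sqrt(sum(proj^2))
  expect_equal(cosang, 1, tolerance = 1e-8)

  fit1 <- fit_pls(X, y, 1)
  L1 <- orthogonalized_loadings(fit1)
  p1 <- fit1$P[, 1]
  expect_equal(abs(sum(L1 * p1)) / sqrt(sum(p1^2)), 1, tolerance = 1e-8)
})

test_that("rmse and r2 match hand-computed values", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(r2(c(1, 2, 3), c(1, 2, 3)), 1)
  ref <- c(1, 2, 3)
  expect_equal(r2(rep(2, 3), ref), 0)
  # hand arithmetic: errors (1, -1, 2) -> RMSE = sqrt(6/3)
  expect_equal(rmse(c(2, 1, 5), ref), sqrt(2))
})
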