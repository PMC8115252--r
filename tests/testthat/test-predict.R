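test_that("cross-validated confound regression never leaks held-out rows", {
  set.seed(24)
  n <- 12
  X <- matrix(rnorm(n * 3), n)
  y <- rnorm(n)
  Zx <- matrix(rnorm(n * 2), n)
  Zy <- matrix(rnorm(n * 2), n)
  folds <- cv_confound_regress(X, y, Zx, Zy)
  # fold-by-fold oracle
  f <- folds[[4]]
  tr <- f$train
  for (j in 1:3) {
    b <- ols_oracle(cbind(1, Zx[tr, ]), X[tr, j])
    expect_close(f$X_adj[, j], X[, j] - cbind(1, Zx) %*% b, 1e-10)
  }
  b_y <- ols_oracle(cbind(1, Zy[tr, ]), y[tr])
  expect_close(f$y_adj, y - as.numeric(cbind(1, Zy) %*% b_y), 1e-10)
  # leakage guard: perturbing a held-out row's confounds leaves training
  # residuals unchanged
  Zx2 <- Zx; Zx2[f$test, ] <- Zx2[f$test, ] + 100
  f2 <- cv_confound_regress(X, y, Zx2, Zy)[[4]]
  expect_equal(f2$X_adj[tr, ], f$X_adj[tr, ])
  expect_false(isTRUE(all.equal(f2$X_adj[f$test, ], f$X_adj[f$test, ])))
  # confounds orthogonal to X (zero coefficients): adjusted = demeaned
  Zo <- matrix(0, n, 0)
  f0 <- cv_confound_regress(X, y, Zo, Zo)[[1]]
  expect_close(f0$X_adj[f0$train, ],
               sweep(X[f0$train, ], 2, colMeans(X[f0$train, ])), 1e-12)
  expect_error(cv_confound_regress(X, y, cbind(Zx, Zx[, 1]), Zy),
               "rank deficient")
})

test_that("LOO-CV SVR nearly interpolates a noiseless linear response", {
  set.seed(25)
  n <- 20
  X <- matrix(rnorm(n * 3), n)
  y <- as.numeric(X %*% c(1, -2, 0.5)) + 5
  fit <- loocv_svr(X, y, config = prediction_config(c_grid = 1000))
  expect_gte(fit$metrics$r2, 0.99)
  expect_equal(nrow(fit$predictions), n)
  expect_error(loocv_svr(X[1:3, ], y[1:3]), "at least 4")
})

test_that("LOO-CV R2 is non-positive on average under the global null", {
  set.seed(26)
  r2 <- replicate(200, {
    X <- matrix(rnorm(12 * 3), 12)
    y <- rnorm(12)
    loocv_svr(X, y, config = prediction_config(c_grid = 0.1))$metrics$r2
  })
  expect_lte(mean(r2), 0)
})

test_that("prediction metrics match hand arithmetic and are consistent", {
  m <- prediction_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$r2, 0.5)
  expect_equal(m$rmse, sqrt(1 / 3))
  expect_equal(m$spearman, 1)
  m2 <- prediction_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m2$r2, 0)
  set.seed(27)
  y <- rnorm(15); yp <- rnorm(15)
  m3 <- prediction_metrics(y, yp)
  expect_equal(m3$r2, 1 - m3$rmse^2 * 15 / sum((y - mean(y))^2),
               tolerance = 1e-12)
  expect_equal(prediction_metrics(y, y),
               tibble::tibble(r2 = 1, rmse = 0, spearman = 1))
  expect_error(prediction_metrics(rep(1, 5), rnorm(5)), "constant")
})

test_that("full-pipeline permutation test attains its minimum p and is deterministic", {
  set.seed(28)
  n <- 14
  X <- matrix(rnorm(n * 2), n)
  y <- as.numeric(X %*% c(2, -1))
  pt <- perm_prediction_test(X, y, config = prediction_config(c_grid = 100),
                             n_perm = 19, seed = 5)
  expect_equal(pt$r2$p, 1 / 20)
  expect_equal(pt$rmse$p, 1 / 20)
  pt2 <- perm_prediction_test(X, y, config = prediction_config(c_grid = 100),
                              n_perm = 19, seed = 5)
  expect_identical(tidy(pt), tidy(pt2))
  expect_equal(pt$r2$tails, "one")
})

test_that("univariate screens recover single-feature structure", {
  set.seed(29)
  n <- 30
  y <- rnorm(n)
  X <- cbind(a = y, b = rnorm(n))
  sc <- univariate_screens(X, y, config = prediction_config(c_grid = 10))
  expect_equal(sc$feature, c("a", "b"))
  expect_equal(sc$pearson_r[1], 1, tolerance = 1e-10)
  expect_gt(sc$single_feature_r2[1], 0.9)
  expect_lt(sc$single_feature_r2[2], 0.2)
  # a feature independent of the response has negligible correlation
  set.seed(30)
  n2 <- 500
  X2 <- cbind(a = rnorm(n2))
  y2 <- rnorm(n2)
  sc2 <- univariate_screens(X2, y2, config = prediction_config(c_grid = 0.1))
  expect_lt(abs(sc2$pearson_r), 3 / sqrt(n2))
})

test_that("model transfer scores targets with the trained linear rule", {
  set.seed(31)
  n <- 16
  X <- matrix(rnorm(n * 3), n)
  y <- as.numeric(X %*% c(1, 0.5, -1)) + rnorm(n, sd = 0.3)
  Z <- matrix(rnorm(n * 2), n)
  cfg <- prediction_config(c_grid = c(0.1, 1))
  # independent linear-scoring oracle: refit by hand and score manually
  idx <- seq_len(n)
  Xa <- neonox:::residualize_on(X, Z, idx)
  ya <- as.numeric(neonox:::residualize_on(matrix(y), Z, idx))
  sc <- neonox:::scale_by_train(Xa, idx)
  C <- neonox:::select_c(sc$X, ya, cfg)
  fit <- neonox:::svr_fit(sc$X, ya, C, cfg$epsilon)
  new_X <- matrix(rnorm(5 * 3), 5)
  new_Z <- matrix(rnorm(5 * 2), 5)
  got <- apply_model(list(X = X, y = y, conf_X = Z, conf_y = Z),
                     new_X, new_Z, cfg, adjust_mode = "within_target")
  new_adj <- neonox:::residualize_on(new_X, new_Z, 1:5)
  new_s <- sweep(sweep(new_adj, 2, sc$mu), 2, sc$sd, `/`)
  expect_close(got$y_pred, as.numeric(new_s %*% fit$w + fit$b), 1e-10)
  # target = training set with training coefficients: in-sample fitted values
  got2 <- apply_model(list(X = X, y = y, conf_X = Z, conf_y = Z),
                      X, Z, cfg, adjust_mode = "train_coefs")
  expect_close(got2$y_pred, as.numeric(sc$X %*% fit$w + fit$b), 1e-10)
  # duplicated training subject receives its in-sample prediction
  dup <- apply_model(list(X = X, y = y, conf_X = Z, conf_y = Z),
                     X[c(3, 3), , drop = FALSE], Z[c(3, 3), , drop = FALSE],
                     cfg, adjust_mode = "train_coefs")
  expect_equal(dup$y_pred[1], got2$y_pred[3], tolerance = 1e-10)
  expect_error(apply_model(list(X = X, y = y), new_X[, 1:2, drop = FALSE]),
               "columns do not align")
})

test_that("inner grid search breaks ties toward the smallest C", {
  # a duplicate-valued grid has identical losses; the first (smallest) wins
  set.seed(32)
  X <- matrix(rnorm(10 * 2), 10)
  y <- rnorm(10)
  cfg <- prediction_config(c_grid = c(0.5, 0.5))
  expect_equal(neonox:::select_c(X, y, cfg), 0.5)
  cfg2 <- prediction_config(c_grid = c(0.001, 0.01, 0.1, 1))
  C <- neonox:::select_c(X, y, cfg2)
  expect_true(C %in% cfg2$c_grid)
})
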