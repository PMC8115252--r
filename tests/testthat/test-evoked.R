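test_that("double-gamma kernel has canonical shape", {
  h <- double_gamma_hrf(dt = 0.01)
  t <- attr(h, "times")
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  # dense-grid argmax near 5 s for the canonical parameters
  expect_equal(t[which.max(h)], 5, tolerance = 0.02)
  # undershoot present and late
  expect_lt(min(h), 0)
  expect_gt(t[which.min(h)], 10)
  h2 <- double_gamma_hrf(dt = 0.01, amplitude = 2)
  expect_equal(as.numeric(h2), as.numeric(2 * h))
  expect_error(double_gamma_hrf(peak_shape = -1), "positive")
})

test_that("design matrix matches an independent fine-grid convolution", {
  hrf <- double_gamma_hrf(dt = 0.1)
  ev <- data.frame(onset = 0, duration = 1)
  n_vols <- 40; tr <- 1.3
  X <- build_design(ev, n_vols, tr, hrf, drift_order = 2)
  expect_equal(colnames(X), c("stimulus", "intercept", "drift1", "drift2"))
  # oracle: direct discrete convolution sum on the same fine grid
  dt <- 0.1
  nf <- ceiling(n_vols * tr / dt) + length(hrf)
  box <- as.numeric(seq_len(nf) * dt - dt < 1)  # 1 s event at t = 0
  conv <- sapply(seq_len(nf), function(i) {
    j <- seq_len(min(i, length(hrf)))
    sum(box[i - j + 1] * hrf[j]) * dt
  })
  oracle <- conv[floor((seq_len(n_vols) - 1) * tr / dt) + 1]
  expect_close(X[, "stimulus"], oracle, 1e-8)
  # no events: stimulus column identically zero
  X0 <- build_design(data.frame(onset = numeric(), duration = numeric()),
                     20, 1, hrf)
  expect_equal(unname(X0[, "stimulus"]), rep(0, 20))
  expect_error(build_design(data.frame(onset = 100, duration = 1), 20, 1, hrf),
               "beyond")
  expect_error(build_design(data.frame(onset = 1, duration = -1), 20, 1, hrf),
               "negative")
})

test_that("voxelwise GLM equals the closed-form normal equations", {
  set.seed(1)
  n_vols <- 30
  X <- cbind(stimulus = rnorm(n_vols), intercept = 1, drift = scale(1:n_vols))
  colnames(X) <- c("stimulus", "intercept", "drift")
  for (rep in 1:5) {
    bold <- array(rnorm(10 * n_vols), c(10, 1, 1, n_vols))
    fit <- glm_fit(bold, X)
    Y <- t(matrix(bold, 10, n_vols))
    B <- ols_oracle(X, Y)
    expect_close(fit$betas$stimulus[, 1, 1], B[1, ], 1e-10)
    expect_close(fit$betas$drift[, 1, 1], B[3, ], 1e-10)
  }
  # exact recovery from noiseless data
  bold2 <- array(0, c(3, 1, 1, n_vols))
  for (v in 1:3) bold2[v, 1, 1, ] <- 2 * X[, 1] + 7
  fit2 <- glm_fit(bold2, X)
  expect_close(fit2$betas$stimulus, array(2, c(3, 1, 1)), 1e-10)
  expect_true(all(fit2$r_squared >= 0 & fit2$r_squared <= 1))
  expect_equal(fit2$df, n_vols - 3)
  Xdup <- cbind(X, X[, 1])
  expect_error(glm_fit(bold2, Xdup), "rank deficient")
})

test_that("group t-map follows the one-sample t formula", {
  mk <- function(v) array(v, c(1, 1, 1))
  t_obs <- group_tmap(list(mk(1), mk(2), mk(3)))
  expect_equal(t_obs[1, 1, 1], 2 * sqrt(3), tolerance = 1e-12)
  expect_warning(t0 <- group_tmap(list(mk(0), mk(0))), "zero-variance")
  expect_equal(t0[1, 1, 1], 0)
  # antisymmetry
  set.seed(2)
  maps <- lapply(1:5, function(i) array(rnorm(24), c(4, 3, 2)))
  neg <- lapply(maps, function(m) -m)
  suppressWarnings(expect_equal(group_tmap(neg), -group_tmap(maps)))
  expect_error(group_tmap(list(mk(1))), "at least two")
})

test_that("spatial-regression amplitude is an OLS slope with intercept", {
  set.seed(3)
  g <- array(rnorm(60), c(5, 4, 3))
  expect_equal(overall_amplitude(3 * g + 7, g), 3, tolerance = 1e-12)
  s <- array(rnorm(60), c(5, 4, 3))
  expect_equal(overall_amplitude(s, g), cov(as.numeric(g), as.numeric(s)) /
                 var(as.numeric(g)), tolerance = 1e-10)
  # affine equivariance: a * map + b -> a * beta
  expect_equal(overall_amplitude(2.5 * s + 4, g),
               2.5 * overall_amplitude(s, g), tolerance = 1e-10)
  # orthogonal to the demeaned group map -> zero slope
  gd <- as.numeric(g) - mean(g)
  orth <- array(rnorm(60), c(5, 4, 3))
  orth <- orth - array(sum(orth * gd) / sum(gd^2) * gd, c(5, 4, 3))
  expect_lt(abs(overall_amplitude(orth, g)), 1e-10)
  expect_error(overall_amplitude(s, array(1, c(5, 4, 3))), "constant")
})

test_that("template expression supports pearson and cosine", {
  m <- array(c(1, 2, 3, 4), c(4, 1, 1))
  tpl <- array(c(1, 0, 0, 1), c(4, 1, 1))
  expect_equal(template_expression(m, tpl, method = "pearson"), 0)
  expect_equal(template_expression(m, m, method = "pearson"), 1)
  expect_equal(template_expression(m, m, method = "cosine"), 1)
  z <- array(c(1, -1, 0, 0), c(4, 1, 1))
  w <- array(c(1, 1, 1, -1), c(4, 1, 1))
  expect_equal(template_expression(z, w, method = "cosine"), 0)
  expect_error(template_expression(m, array(1, c(4, 1, 1)), method = "pearson"),
               "constant")
})

test_that("effective-number-of-tests estimators match hand arithmetic", {
  expect_equal(effective_tests(diag(10), "liji")$m_eff, 10)
  expect_equal(effective_tests(diag(10), "nyholt")$m_eff, 10)
  ones <- matrix(1, 6, 6)
  expect_equal(effective_tests(ones, "liji")$m_eff, 1)
  expect_equal(effective_tests(ones, "nyholt")$m_eff, 1)
  # m = 2, r = 0.6: eigenvalues {1.6, 0.4}, nyholt m_eff = 1.64
  r2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(effective_tests(r2, "nyholt")$m_eff, 1.64, tolerance = 1e-12)
  expect_equal(effective_tests(r2, "nyholt", family_alpha = 0.05)$corrected_alpha,
               0.05 / 1.64, tolerance = 1e-12)
  expect_error(effective_tests(matrix(c(1, 2, 3, 1), 2)), "symmetric")
})
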