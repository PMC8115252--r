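test_that("QC thresholding removes out-of-range voxels per parameter", {
  mk <- array(c(0.5, 3.5, 2.9, -0.2), c(4, 1, 1))
  qc <- qc_threshold_map(mk, "MK")
  expect_equal(qc$removed, 2)
  expect_true(is.na(qc$map[2, 1, 1]) && is.na(qc$map[4, 1, 1]))
  md <- array(abs(rnorm(10)), c(10, 1, 1))
  expect_equal(qc_threshold_map(md, "MD")$removed, 0)
  fa <- array(c(0.3, 1.2, -0.1, 0.8), c(4, 1, 1))
  expect_equal(qc_threshold_map(fa, "FA")$removed, 2)
})

test_that("tract means respect the probability threshold and QC mask", {
  pmap <- array(c(0.005, 0.02, 0.5, 1), c(4, 1, 1))
  vals <- array(c(100, 2, 4, 6), c(4, 1, 1))
  expect_equal(tract_mean(vals, pmap, 0.01), 4)  # voxel 1 excluded
  expect_equal(tract_mean(array(7, c(4, 1, 1)), pmap), 7)
  vals_na <- vals; vals_na[2, 1, 1] <- NA
  expect_equal(tract_mean(vals_na, pmap, 0.01), 5)
  set.seed(33)
  v2 <- array(rnorm(24), c(4, 3, 2)); p2 <- array(runif(24), c(4, 3, 2))
  expect_equal(tract_mean(v2, p2, 0.3), mean(v2[p2 >= 0.3]))
  expect_error(tract_mean(vals, array(0, c(4, 1, 1)), 0.5), "empty")
})

test_that("adjusted correlation equals the closed-form partial correlation", {
  set.seed(34)
  n <- 40
  z <- rnorm(n)
  x <- 0.5 * z + rnorm(n)
  y <- -0.3 * z + rnorm(n)
  expect_equal(adjusted_correlation(x, y), cor(x, y), tolerance = 1e-12)
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  oracle <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  expect_equal(adjusted_correlation(x, y, matrix(z)), oracle,
               tolerance = 1e-10)
  expect_error(adjusted_correlation(x, y, matrix(x)), "zero-variance")
})

test_that("exploratory screen is FWER-dominant and counts 48 tests", {
  co <- gen_cohort(cohort_spec(n_subjects = 40, seed = 35))
  Z <- as.matrix(co$confounds[, c("dmri_motion", "dmri_noisy_vox", "dmri_tbv")])
  sc <- exploratory_screen(co$subjects$amplitude_true,
                           dplyr::select(co$tracts, -subject_id), Z,
                           n_perm = 200, seed = 1)
  res <- tidy(sc)
  expect_equal(nrow(res), 48)
  expect_equal(sort(unique(res$parameter)), c("FA", "MD", "MK"))
  expect_equal(sort(unique(res$tract)), sort(tract_labels()))
  expect_true(all(res$fwer_p >= res$p - 1e-12))
  expect_true(all(res$p > 0 & res$p <= 1))
  sc2 <- exploratory_screen(co$subjects$amplitude_true,
                            dplyr::select(co$tracts, -subject_id), Z,
                            n_perm = 200, seed = 1)
  expect_identical(tidy(sc2), res)
})

test_that("an injected association survives the max-statistic screen", {
  # 47 realistically inter-correlated null features plus one feature with
  # true adjusted correlation 0.3 at n = 215
  hits <- sapply(1:60, function(s) {
    co <- gen_cohort(cohort_spec(n_subjects = 215, seed = 1000 + s))
    feats <- as.matrix(dplyr::select(co$tracts, -subject_id))
    y <- with_seed_local(s, rnorm(215))
    feats[, "atr_md"] <- with_seed_local(
      2000 + s, 0.3 * scale(y) + sqrt(1 - 0.09) * rnorm(215))
    sc <- exploratory_screen(y, feats, n_perm = 500, seed = 3000 + s)
    tidy(sc)$significant[tidy(sc)$tract == "atr" & tidy(sc)$parameter == "MD"]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("PC1 pooling matches analytic structure", {
  set.seed(36)
  one <- matrix(rnorm(30), 30, 1)
  pc <- md_pc1(one)
  expect_equal(pc$variance_fraction, 1)
  expect_close(pc$scores, as.numeric(scale(one)), 1e-10)
  two <- cbind(one, 3 * one + 5)
  pc2 <- md_pc1(two)
  expect_equal(pc2$variance_fraction, 1, tolerance = 1e-12)
  # sign convention: mean loading positive
  expect_gt(mean(pc2$loadings), 0)
  expect_gt(cor(pc2$scores, one[, 1]), 0.999)
  expect_error(md_pc1(cbind(one, rep(1, 30))), "zero-variance")
})

test_that("directional confirmatory test reports polarity and dominance", {
  set.seed(37)
  n <- 17
  m <- rnorm(n)
  md <- sapply(1:5, function(j) -0.5 * m + rnorm(n, sd = 0.4))
  colnames(md) <- designated_tracts()
  amp <- 1.5 * m + rnorm(n, sd = 0.8)
  ct <- confirmatory_test(amp, md, n_perm = 400, seed = 2)
  expect_equal(nrow(ct$polarity), 5)
  expect_lt(ct$pc1_r, 0)
  expect_lt(ct$p, 0.05)
  expect_gt(ct$variance_fraction, 0.3)
  # observed r positive under hypothesised negative direction: p >= 0.5
  ct_flip <- confirmatory_test(-amp, md, n_perm = 400, seed = 2)
  expect_gte(ct_flip$p, 0.5)
  g <- glance(ct)
  expect_equal(g$direction, "negative")
})

test_that("subset combinations enumerate and match a brute-force oracle", {
  set.seed(38)
  n <- 17
  M3 <- matrix(rnorm(n * 3), n); colnames(M3) <- c("a", "b", "c")
  amp <- rnorm(n)
  sub3 <- subset_combination_analysis(amp, M3, target_subset = "a")
  expect_equal(nrow(tidy(sub3)), 7)
  best <- subset_combination_analysis(
    amp, M3, target_subset = colnames(M3)[
      which(bitwAnd(tidy(sub3)$bitmask[which.max(tidy(sub3)$r2)],
                    bitwShiftL(1L, 0:2)) > 0)])
  expect_equal(best$percentile, 100)
  # 4-tract universe: every subset equals the independent PCA + partial
  # correlation recomputation
  M4 <- matrix(rnorm(n * 4), n); colnames(M4) <- c("a", "b", "c", "d")
  Z <- matrix(rnorm(n * 2), n)
  res <- subset_combination_analysis(amp, M4, Z, target_subset = c("b", "d"))
  tab <- tidy(res)
  expect_equal(nrow(tab), 15)
  for (bm in tab$bitmask) {
    S <- which(bitwAnd(bm, bitwShiftL(1L, 0:3)) > 0)
    pc <- md_pc1(neonox:::residualize_on(M4[, S, drop = FALSE], Z, 1:n),
                 standardize = TRUE)
    r_o <- adjusted_correlation(pc$scores, amp, Z)
    expect_equal(tab$r2[tab$bitmask == bm], r_o^2, tolerance = 1e-8)
  }
  # percentile is a rank statistic: invariant to monotone rescaling of r2
  pct_rank <- 100 * sum(tab$r2 <= res$target_r2 + 1e-12) / nrow(tab)
  expect_equal(res$percentile, pct_rank)
})

test_that("tract profile comparison is a plain Pearson correlation", {
  set.seed(39)
  a <- rnorm(16); b <- 0.5 * a + rnorm(16, sd = 0.3)
  expect_equal(compare_tract_profiles(a, a), 1)
  expect_equal(compare_tract_profiles(a, -a + 2), -1)
  expect_equal(compare_tract_profiles(a, b), cor(a, b), tolerance = 1e-12)
  expect_error(compare_tract_profiles(a, b[1:5]), "length mismatch")
})
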