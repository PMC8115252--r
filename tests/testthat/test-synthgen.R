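test_that("cohort generation is a pure function of spec and seed", {
  spec <- cohort_spec(n_subjects = 12, seed = 7)
  a <- gen_cohort(spec)
  b <- gen_cohort(spec)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$rsn, b$rsn)
  expect_identical(a$tracts, b$tracts)
  expect_identical(a$confounds, b$confounds)
  c2 <- gen_cohort(cohort_spec(n_subjects = 12, seed = 8))
  expect_false(identical(a$subjects$m, c2$subjects$m))
  expect_equal(nrow(a$subjects), 12)
  expect_equal(ncol(a$tracts) - 1L, 48)
})

test_that("null-loading cohorts have no latent-feature correlation", {
  spec <- cohort_spec(
    n_subjects = 1e4,
    rsn_loadings = setNames(rep(0, 9), names(cohort_spec()$rsn_loadings)),
    tract_md_loadings = rep(0, 16), tract_fa_loadings = rep(0, 16),
    tract_mk_loadings = rep(0, 16),
    tract_shared_sd = list(md = 0, fa = 0, mk = 0),
    seed = 11)
  co <- gen_cohort(spec)
  feats <- cbind(as.matrix(co$rsn[, -1]), as.matrix(co$tracts[, -1]))
  r <- abs(cor(co$subjects$m, feats))
  expect_lt(max(r), 0.03)
})

test_that("latent-tract correlation matches the linear-Gaussian closed form", {
  # MD = baseline - 0.5 m + e with unit sds: cor(MD, m) = -0.5/sqrt(1.25)
  spec <- cohort_spec(
    n_subjects = 1e4, latent_sd = 1,
    tract_md_loadings = rep(-0.5, 16),
    tract_noise_sd = list(md = 1, fa = 0.03, mk = 0.05),
    tract_shared_sd = list(md = 0, fa = 0, mk = 0),
    seed = 13)
  co <- gen_cohort(spec)
  r <- cor(co$subjects$m, co$tracts$atr_md)
  expect_equal(r, -0.5 / sqrt(1.25), tolerance = 0.02 / 0.447)
})

test_that("template generator hits target spatial correlations", {
  geom <- tiny_geom()
  tpl <- gen_templates(geom, k_rsn = 4, adult_target_corrs = c(1, 0, 0.6),
                       seed = 5)
  g <- tpl$group_map[geom$mask]
  r <- sapply(tpl$adult_maps, function(a) cor(a[geom$mask], g))
  expect_equal(r[1], 1, tolerance = 1e-10)
  expect_lt(abs(r[2]), 0.05)
  expect_lt(abs(r[3] - 0.6), 0.05)
  # rho = 1 template equals the group map up to positive scaling
  fit <- lm(tpl$adult_maps[[1]][geom$mask] ~ g)
  expect_gt(coef(fit)[2], 0)
  # RSN maps mutually near-orthogonal
  M <- sapply(tpl$rsn_maps, function(m) m[geom$mask])
  C <- cor(M)
  expect_lt(max(abs(C[upper.tri(C)])), 0.2)
  tpl2 <- gen_templates(geom, k_rsn = 4, adult_target_corrs = c(1, 0, 0.6),
                        seed = 5)
  expect_identical(tpl$group_map, tpl2$group_map)
  expect_error(gen_templates(geom, 2, adult_target_corrs = 1.5),
               "\\[-1, 1\\]")
})

test_that("default event schedule has ten trials spaced at least 25 s", {
  ev <- default_event_table(seed = 3)
  expect_equal(nrow(ev), 10)
  expect_true(all(ev$duration == 1))
  expect_gte(ev$onset[1], 0)
  expect_true(all(diff(ev$onset) >= 25))
})

test_that("noiseless task run reproduces the generative amplitude end to end", {
  geom <- tiny_geom()
  tpl <- tiny_templates()
  ev <- default_event_table(seed = 3)
  quiet <- list(thermal_sd = 0, ar1 = 0, drift_amp = 0, baseline = 100)
  run <- gen_task_run(2, tpl$group_map, ev, tr = 1.3, n_vols = 260,
                      noise = quiet, mask = geom$mask, seed = 1)
  fit <- glm_fit(run, build_design(ev, 260, 1.3), geom$mask)
  amp <- overall_amplitude(fit$betas$stimulus, tpl$group_map, geom$mask)
  expect_lt(abs(amp - 2), 1e-6)
  # zero amplitude, zero noise: constant over time
  ev0 <- data.frame(onset = 5, duration = 1)
  run0 <- gen_task_run(0, tpl$group_map, ev0, tr = 1.3, n_vols = 50,
                       noise = quiet, mask = geom$mask, seed = 1)
  expect_equal(max(apply(matrix(run0, prod(dim(run0)[1:3]), 50), 1, sd)), 0)
  expect_error(gen_task_run(1, tpl$group_map,
                            data.frame(onset = 400, duration = 1),
                            tr = 1.3, n_vols = 100, noise = quiet),
               "beyond the end")
})

test_that("rest generator calibrates network MAD amplitudes", {
  geom <- phantom_geometry(c(6, 6, 4))
  tpl <- gen_templates(geom, k_rsn = 2, seed = 9)
  amps <- c(1.5, 0.7)
  run <- gen_rest_run(amps, tpl$rsn_maps, n_vols = 1e5,
                      noise = list(thermal_sd = 0, ar1 = 0, baseline = 0),
                      mask = geom$mask, seed = 21)
  ts <- spatial_regression_timeseries(run, tpl$rsn_maps, geom$mask)
  got <- apply(ts$series, 1, mad_amplitude)
  expect_lt(max(abs(got / amps - 1)), 0.01)
  # all-zero amplitudes, zero noise: constant data
  run0 <- gen_rest_run(c(0, 0), tpl$rsn_maps, n_vols = 30,
                       noise = list(thermal_sd = 0, ar1 = 0, baseline = 5),
                       mask = geom$mask, seed = 2)
  expect_true(all(run0 %in% c(0, 5)))
  run_a <- gen_rest_run(amps, tpl$rsn_maps, n_vols = 40, mask = geom$mask,
                        seed = 3)
  run_b <- gen_rest_run(amps, tpl$rsn_maps, n_vols = 40, mask = geom$mask,
                        seed = 3)
  expect_identical(run_a, run_b)
  expect_error(gen_rest_run(c(1, 2, 3), tpl$rsn_maps), "one amplitude per")
})

test_that("motion tables are reproducible and sized correctly", {
  m <- gen_motion_table(50, seed = 4)
  expect_identical(m, gen_motion_table(50, seed = 4))
  expect_equal(dim(as.matrix(m)), c(50L, 6L))
})

test_that("dataset writer produces a checksum manifest and round trips", {
  out <- withr::local_tempdir()
  co <- gen_cohort(cohort_spec(n_subjects = 4, seed = 2))
  tpl <- gen_templates(phantom_geometry(c(6, 6, 4)), k_rsn = 2,
                       adult_target_corrs = 0.5, seed = 2)
  man <- write_dataset(co, tpl, out_dir = out)
  expect_equal(nrow(man), length(list.files(out)) - 1L)  # manifest.json itself
  back <- read_volume(file.path(out, "group_map.nii.gz"))
  expect_equal(as.numeric(back), as.numeric(tpl$group_map))
  man2 <- write_dataset(co, tpl, out_dir = out)
  expect_identical(man$md5, man2$md5)
  tab <- read_table(file.path(out, "subjects.tsv"),
                    schema = c(subject_id = "character", m = "numeric"))
  expect_equal(tab$m, co$subjects$m, tolerance = 1e-12)
})
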