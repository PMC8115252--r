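#' Pipeline run configuration
#'
#' Desk-scale defaults for the full simulated-cohort pipeline: a small
#' phantom grid, a local-style cohort (n = 18) with measured task and rest
#' runs, and a large tabular cohort (n = 215) used for the exploratory arm.
#'
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param out_dir Output directory.
#' @param n_local,n_large Cohort sizes.
#' @param grid_shape Phantom grid.
#' @param tr Repetition time (s).
#' @param n_vols_task,n_vols_rest Run lengths (volumes).
#' @param n_perm Permutation budget for the scalar tests.
#' @param n_perm_cluster Permutation budget for cluster inference.
#' @param cluster_forming_p Cluster-defining threshold; the desk-scale
#'   default (0.01) is coarser than the conventional 0.001 so that the
#'   permutation-rank z transform can reach it at the default permutation
#'   budget.
#' @param alpha Significance level.
#' @param prediction A [prediction_config()].
#' @param cohort Optional [cohort_spec()] overriding the local cohort spec.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("neonox_run_"),
                       n_local = 18, n_large = 215,
                       grid_shape = c(16L, 16L, 12L), tr = 1.3,
                       n_vols_task = 260, n_vols_rest = 300,
                       n_perm = 500, n_perm_cluster = 500,
                       cluster_forming_p = 0.01, alpha = 0.05,
                       prediction = prediction_config(), cohort = NULL) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_local = n_local, n_large = n_large,
                 grid_shape = as.integer(grid_shape), tr = tr,
                 n_vols_task = n_vols_task, n_vols_rest = n_vols_rest,
                 n_perm = n_perm, n_perm_cluster = n_perm_cluster,
                 cluster_forming_p = cluster_forming_p,
                 alpha = alpha, prediction = prediction, cohort = cohort),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `prediction` may
#' be a mapping with `epsilon` and `c_grid`.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pc <- if (!is.null(y$prediction)) {
    do.call(prediction_config, y$prediction)
  } else prediction_config()
  y$prediction <- NULL
  do.call(run_config, c(y, list(prediction = pc)))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  x <- unclass(config)
  x$out_dir <- NULL  # path is not part of the scientific configuration
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

# CSF-like and WM-reference ROIs just outside the brain mask (CSF
# surrounds the brain; the outer shell carries no evoked or network
# signal, as the reference ROIs should).
roi_masks <- function(geometry) {
  d <- geometry$grid_shape
  ctr <- (d + 1) / 2
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  r <- sqrt(((g$x - ctr[1]) / (d[1] / 2))^2 + ((g$y - ctr[2]) / (d[2] / 2))^2 +
              ((g$z - ctr[3]) / (d[3] / 2))^2)
  r <- array(r, dim = d)
  list(csf = !geometry$mask & r <= 1.25,
       wm = !geometry$mask & r > 1.25 & r <= 1.55)
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(k)) %% 2147483629)
}

#' Run the simulated-cohort analysis pipeline
#'
#' Executes the requested stage(s) of the full chain on synthetic data:
#' `simulate` (cohorts + templates), `evoked` (task-run GLM, overall
#' amplitudes, group map, cluster inference, template expression),
#' `rsn` (resting-run network amplitudes and confounds), `predict`
#' (LOO-CV SVR with permutation inference), `structfun`
#' (exploratory screen on the large cohort with model-transferred
#' amplitudes, confirmatory arm on the local cohort, subset analysis), or
#' `all`. Writes stage outputs under `config$out_dir` and returns (and
#' writes) a report containing every statistic, p-value and seed.
#'
#' @param config A [run_config()].
#' @param stage One of `"simulate"`, `"evoked"`, `"rsn"`, `"predict"`,
#'   `"structfun"`, `"all"`.
#' @return The report, an invisible named list (also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config = run_config(),
                         stage = c("all", "simulate", "evoked", "rsn",
                                   "predict", "structfun")) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") {
    c("simulate", "evoked", "rsn", "predict", "structfun")
  } else stage
  state_path <- file.path(config$out_dir, "state.rds")
  state <- if (file.exists(state_path)) readRDS(state_path) else list()
  report <- list(seed = config$seed, config_hash = config_hash(config),
                 stages = list())
  report_path <- file.path(config$out_dir, "report.json")
  if (file.exists(report_path)) {
    prev <- jsonlite::read_json(report_path)
    if (!is.null(prev$stages)) report$stages <- prev$stages
  }

  for (st in stages) {
    t0 <- Sys.time()
    need <- switch(st, simulate = character(), evoked = "simulate",
                   rsn = "simulate", predict = c("evoked", "rsn"),
                   structfun = c("predict"))
    missing <- setdiff(need, names(state))
    if (length(missing) > 0L) {
      stop(sprintf("stage '%s' requires prior stage(s): %s", st,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    state <- switch(st,
      simulate = stage_simulate(config, state),
      evoked = stage_evoked(config, state),
      rsn = stage_rsn(config, state),
      predict = stage_predict(config, state),
      structfun = stage_structfun(config, state))
    report$stages[[st]] <- c(state[[st]]$summary,
                             list(elapsed_s = as.numeric(Sys.time() - t0,
                                                         units = "secs")))
    saveRDS(state, state_path)
  }
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(report)
}

stage_simulate <- function(config, state) {
  geom <- phantom_geometry(config$grid_shape)
  spec_local <- config$cohort %||%
    cohort_spec(n_subjects = config$n_local,
                seed = derive_seed(config$seed, 1L))
  spec_large <- spec_local
  spec_large$n_subjects <- as.integer(config$n_large)
  spec_large$seed <- derive_seed(config$seed, 2L)
  local <- gen_cohort(spec_local)
  large <- gen_cohort(spec_large)
  templates <- gen_templates(geom, k_rsn = length(spec_local$rsn_loadings),
                             adult_target_corrs = c(0.6, 0.0),
                             seed = derive_seed(config$seed, 3L))
  manifest <- write_dataset(local, templates,
                            out_dir = file.path(config$out_dir, "local"))
  write_table(large$tracts, file.path(config$out_dir, "large_tracts.tsv"))
  state$simulate <- list(
    geom = geom, local = local, large = large, templates = templates,
    summary = list(n_local = nrow(local$subjects),
                   n_large = nrow(large$subjects),
                   n_files = nrow(manifest)))
  state
}

stage_evoked <- function(config, state) {
  sim <- state$simulate
  geom <- sim$geom
  events <- default_event_table(seed = derive_seed(config$seed, 4L))
  hrf <- double_gamma_hrf()
  design <- build_design(events, config$n_vols_task, config$tr, hrf)
  rois <- roi_masks(geom)
  n <- nrow(sim$local$subjects)
  beta_maps <- vector("list", n)
  task_conf <- vector("list", n)
  for (i in seq_len(n)) {
    # runs cover the full grid so the extra-cerebral reference ROIs carry
    # noise rather than zeros; evoked signal lives only inside the mask
    run <- gen_task_run(sim$local$subjects$amplitude_true[i],
                        sim$templates$group_map, events,
                        tr = config$tr, n_vols = config$n_vols_task,
                        seed = derive_seed(config$seed, 100L + i))
    fit <- glm_fit(run, design)
    beta_maps[[i]] <- fit$betas$stimulus
    motion <- gen_motion_table(config$n_vols_task,
                               seed = derive_seed(config$seed, 200L + i))
    m24 <- motion_expansion(motion)
    task_conf[[i]] <- tibble::tibble(
      subject_id = sim$local$subjects$subject_id[i],
      task_mean_fd = framewise_displacement(motion)$mean_fd,
      task_stim_corr = stimulus_correlated_motion(design[, "stimulus"], m24),
      task_csf_amp = roi_amplitude(fit$betas$stimulus, rois$csf, "mean_beta"))
  }
  tmap <- group_tmap(beta_maps, geom$mask)
  amp <- vapply(beta_maps, overall_amplitude, numeric(1),
                group_map = tmap, mask = geom$mask)
  clus <- cluster_inference(beta_maps, geom$mask, geom$voxel_size_mm,
                            cluster_forming_p = config$cluster_forming_p,
                            n_perm = config$n_perm_cluster,
                            seed = derive_seed(config$seed, 5L))
  expr <- purrr::map_dfr(seq_along(sim$templates$adult_maps), function(k) {
    tibble::tibble(
      template = sprintf("adult_%02d", k),
      subject_id = sim$local$subjects$subject_id,
      pearson = vapply(beta_maps, template_expression, numeric(1),
                       template = sim$templates$adult_maps[[k]],
                       mask = geom$mask, method = "pearson"),
      cosine = vapply(beta_maps, template_expression, numeric(1),
                      template = sim$templates$adult_maps[[k]],
                      mask = geom$mask, method = "cosine"))
  })
  expr_tests <- purrr::map_dfr(split(expr, expr$template), function(g) {
    dplyr::mutate(tidy(group_expression_test(
      g$pearson, n_perm = config$n_perm,
      seed = derive_seed(config$seed, 6L))), template = g$template[1])
  })
  amps <- tibble::tibble(subject_id = sim$local$subjects$subject_id,
                         amplitude = amp)
  write_table(amps, file.path(config$out_dir, "amplitudes.tsv"))
  write_table(dplyr::bind_rows(task_conf),
              file.path(config$out_dir, "task_confounds.tsv"))
  write_table(expr, file.path(config$out_dir, "template_expression.tsv"))
  write_volume(tmap, file.path(config$out_dir, "group_tmap.nii.gz"))
  write_volume(clus$thresholded_map,
               file.path(config$out_dir, "group_clusters.nii.gz"))
  state$evoked <- list(
    amplitudes = amps, task_confounds = dplyr::bind_rows(task_conf),
    tmap = tmap, clusters = clus, expression = expr,
    summary = list(
      amplitude_range = range(amp),
      amplitude_truth_cor = cor(amp, sim$local$subjects$amplitude_true),
      n_clusters = nrow(clus$clusters),
      n_significant_clusters = sum(clus$clusters$significant),
      expression_tests = as.list(setNames(expr_tests$p.value,
                                          expr_tests$template))))
  state
}

stage_rsn <- function(config, state) {
  sim <- state$simulate
  geom <- sim$geom
  rois <- roi_masks(geom)
  n <- nrow(sim$local$subjects)
  rsn_true <- as.matrix(dplyr::select(sim$local$rsn, -"subject_id"))
  out <- vector("list", n)
  conf <- vector("list", n)
  for (i in seq_len(n)) {
    amps_i <- pmax(rsn_true[i, ], 0.05)
    run <- gen_rest_run(amps_i, sim$templates$rsn_maps, tr = config$tr,
                        n_vols = config$n_vols_rest,
                        seed = derive_seed(config$seed, 300L + i))
    a <- rsn_amplitudes(run, sim$templates$rsn_maps, geom$mask)
    out[[i]] <- dplyr::mutate(a, subject_id = sim$local$subjects$subject_id[i],
                              .before = 1)
    motion <- gen_motion_table(config$n_vols_rest,
                               seed = derive_seed(config$seed, 400L + i))
    conf[[i]] <- tibble::tibble(
      subject_id = sim$local$subjects$subject_id[i],
      rest_mean_fd = framewise_displacement(motion)$mean_fd,
      rest_csf_amp = roi_amplitude(run, rois$csf, "mad_timeseries"),
      rest_wm_amp = roi_amplitude(run, rois$wm, "mad_timeseries"))
  }
  amp_tab <- dplyr::bind_rows(out)
  wide <- tidyr::pivot_wider(amp_tab[, c("subject_id", "network", "mad")],
                             names_from = "network", values_from = "mad",
                             names_prefix = "rsn_")
  write_table(amp_tab, file.path(config$out_dir, "rsn_amplitudes.tsv"))
  write_table(dplyr::bind_rows(conf),
              file.path(config$out_dir, "rest_confounds.tsv"))
  truth_cor <- cor(as.numeric(as.matrix(wide[, -1])), as.numeric(rsn_true))
  state$rsn <- list(
    amplitudes = amp_tab, wide = wide, rest_confounds = dplyr::bind_rows(conf),
    summary = list(mean_outlier_fraction = mean(amp_tab$outlier_fraction),
                   amplitude_truth_cor = truth_cor))
  state
}

stage_predict <- function(config, state) {
  X <- as.matrix(state$rsn$wide[, -1])
  y <- state$evoked$amplitudes$amplitude
  conf_X <- as.matrix(state$rsn$rest_confounds[, -1])
  conf_y <- as.matrix(state$evoked$task_confounds[, -1])
  pt <- perm_prediction_test(X, y, conf_X, conf_y, config$prediction,
                             n_perm = config$n_perm,
                             seed = derive_seed(config$seed, 7L))
  uni <- univariate_screens(X, y, conf_X, conf_y, config$prediction)
  write_table(tidy(pt$observed), file.path(config$out_dir, "predictions.tsv"))
  write_table(uni, file.path(config$out_dir, "univariate_screens.tsv"))
  state$predict <- list(
    perm = pt, observed = pt$observed, univariate = uni,
    X = X, y = y, conf_X = conf_X, conf_y = conf_y,
    summary = list(r2 = pt$observed$metrics$r2,
                   rmse = pt$observed$metrics$rmse,
                   spearman = pt$observed$metrics$spearman,
                   p_r2 = pt$r2$p, p_rmse = pt$rmse$p,
                   p_spearman = pt$spearman$p,
                   best_single_feature = uni$feature[
                     which.max(uni$single_feature_r2)]))
  state
}

stage_structfun <- function(config, state) {
  sim <- state$simulate
  large <- sim$large
  # model transfer: predicted amplitudes for the large cohort
  large_X <- as.matrix(dplyr::select(large$rsn, -"subject_id"))
  large_conf <- as.matrix(large$confounds[, c("rest_mean_fd", "rest_csf_amp",
                                              "rest_wm_amp")])
  pred <- apply_model(
    train = list(X = state$predict$X, y = state$predict$y,
                 conf_X = state$predict$conf_X, conf_y = state$predict$conf_y),
    new_X = large_X, new_conf_X = large_conf, config = config$prediction)
  dmri_conf_large <- as.matrix(large$confounds[, c("dmri_motion",
                                                   "dmri_noisy_vox", "dmri_tbv")])
  feats_large <- dplyr::select(large$tracts, -"subject_id")
  screen <- exploratory_screen(pred$y_pred, feats_large, dmri_conf_large,
                               alpha = config$alpha, n_perm = config$n_perm,
                               seed = derive_seed(config$seed, 8L))
  md_cols <- paste0(designated_tracts(), "_md")
  pc_large <- md_pc1(residualize_on(as.matrix(feats_large[, md_cols]),
                                    dmri_conf_large,
                                    seq_len(nrow(feats_large))))
  r_large <- adjusted_correlation(pc_large$scores, pred$y_pred,
                                  dmri_conf_large)
  # confirmatory arm in the local cohort; one subject dropped to mirror
  # incomplete dMRI (row-completeness filtering)
  keep <- seq_len(nrow(sim$local$tracts) - 1L)
  local_md <- as.matrix(sim$local$tracts[keep, md_cols])
  local_amp <- state$evoked$amplitudes$amplitude[keep]
  dmri_conf_local <- as.matrix(sim$local$confounds[keep, c("dmri_motion",
                                                           "dmri_noisy_vox",
                                                           "dmri_tbv")])
  confirm <- confirmatory_test(local_amp, local_md, dmri_conf_local,
                               direction = "negative", n_perm = config$n_perm,
                               seed = derive_seed(config$seed, 9L))
  all_md <- as.matrix(sim$local$tracts[keep, paste0(tract_labels(), "_md")])
  subsets <- subset_combination_analysis(local_amp, all_md, dmri_conf_local,
                                         target_subset = paste0(
                                           designated_tracts(), "_md"))
  md_rows <- screen$results$parameter == "MD"
  r_local16 <- vapply(seq_len(ncol(all_md)), function(j)
    adjusted_correlation(all_md[, j], local_amp, dmri_conf_local), numeric(1))
  profile_r <- compare_tract_profiles(screen$results$r[md_rows], r_local16)
  write_table(tidy(screen), file.path(config$out_dir, "screen.tsv"))
  write_table(tidy(subsets), file.path(config$out_dir, "subset_r2.tsv"))
  state$structfun <- list(
    screen = screen, confirm = confirm, subsets = subsets,
    predicted = pred,
    summary = list(
      n_tests = nrow(screen$results),
      n_fwer_significant = sum(screen$results$significant),
      exploratory_pc1_r = r_large,
      exploratory_pc1_variance_fraction = pc_large$variance_fraction,
      confirmatory_pc1_r = confirm$pc1_r,
      confirmatory_p = confirm$p,
      confirmatory_variance_fraction = confirm$variance_fraction,
      n_negative_polarity = sum(confirm$polarity$sign == "negative"),
      subset_percentile = subsets$percentile,
      target_r2 = subsets$target_r2,
      md_profile_similarity = profile_r))
  state
}
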