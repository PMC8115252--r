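#' Tract and network label sets
#'
#' `tract_labels()` returns the 16 bilateral white-matter tract abbreviations
#' used throughout (acoustic radiation through uncinate fasciculus);
#' `designated_tracts()` the five functionally relevant tracts whose mean
#' diffusivity carries the strongest simulated structure-function coupling
#' (anterior/superior thalamic radiations, corticospinal tract, forceps
#' minor, uncinate fasciculus); `rsn_labels()` the nine resting-state network
#' names (medial/occipital visual, left/right auditory, two somatomotor,
#' default mode, dorsal attention, executive control).
#' @return Character vector of labels.
#' @export
tract_labels <- function() {
  c("ar", "atr", "cgc", "cgh", "cst", "fma", "fmi", "for",
    "ifo", "ilf", "mcp", "ml", "ptr", "slf", "str", "unc")
}

#' @rdname tract_labels
#' @export
designated_tracts <- function() c("atr", "cst", "fmi", "str", "unc")

#' @rdname tract_labels
#' @export
rsn_labels <- function() {
  c("vnm", "vnop", "anr", "anl", "smn1", "smn2", "dmn", "dan", "ecn")
}

#' Phantom acquisition geometry
#'
#' A small 3D grid standing in for the 2 mm-isotropic neonatal acquisition
#' space, with an ellipsoidal analysis mask.
#'
#' @param grid_shape Integer triple of voxels per axis (all >= 4).
#' @param voxel_size_mm Positive real triple (mm).
#' @param mask Optional logical array; default is the inscribed ellipsoid.
#' @return List of class `phantom_geometry` with fields `grid_shape`,
#'   `voxel_size_mm`, `mask`.
#' @export
phantom_geometry <- function(grid_shape = c(24L, 24L, 16L),
                             voxel_size_mm = c(2, 2, 2), mask = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L)) {
    stop("grid_shape must be three integers >= 4", call. = FALSE)
  }
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop("voxel_size_mm must be three positive reals", call. = FALSE)
  }
  if (is.null(mask)) {
    ctr <- (grid_shape + 1) / 2
    g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                     z = seq_len(grid_shape[3]))
    r <- ((g$x - ctr[1]) / (grid_shape[1] / 2))^2 +
      ((g$y - ctr[2]) / (grid_shape[2] / 2))^2 +
      ((g$z - ctr[3]) / (grid_shape[3] / 2))^2
    mask <- array(r <= 1, dim = grid_shape)
  }
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 mask = mask),
            class = "phantom_geometry")
}

#' Specification of a synthetic cohort
#'
#' Defines the linear-Gaussian latent model used by [gen_cohort()]. A single
#' per-subject maturity factor `m ~ N(0, latent_sd^2)` drives (a) the true
#' overall noxious-evoked amplitude
#' `a = amplitude_intercept + amplitude_loading * m + noise`, (b) positive
#' loadings on the nine resting-state network amplitudes (largest for the
#' somatomotor networks), and (c) negative loadings on tract-mean MD and
#' positive loadings on FA/MK across 16 tracts, strongest for the five
#' designated tracts. Confound and clinical variables are generated with
#' configurable couplings (default 0).
#'
#' Default sizes and scales mirror a small noxious-stimulation cohort
#' (n = 18) with amplitude mean ~2 and SD ~1.9 and a signal fraction of 0.6
#' (`amplitude_loading^2 / (amplitude_loading^2 + amplitude_noise_sd^2)`).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param latent_sd SD of the maturity factor.
#' @param amplitude_intercept,amplitude_loading,amplitude_noise_sd True
#'   amplitude model parameters.
#' @param rsn_loadings,rsn_baselines Numeric vectors (length K) of network
#'   loadings on `m` and baseline amplitudes.
#' @param rsn_noise_sd Network amplitude noise SD.
#' @param tract_md_baselines,tract_md_loadings,tract_fa_baselines,
#'   tract_fa_loadings,tract_mk_baselines,tract_mk_loadings Length-16
#'   vectors; MD in units of 1e-3 mm^2/s.
#' @param tract_noise_sd Named list with per-parameter noise SDs
#'   (`md`, `fa`, `mk`).
#' @param tract_shared_sd Named list with per-parameter SDs of a shared
#'   (maturity-independent) factor loading equally on all 16 tracts; this
#'   reproduces the strong inter-tract correlation of neonatal diffusion
#'   parameters. Set to 0 to make tract features conditionally independent
#'   given `m`.
#' @param confound_couplings,clinical_couplings Named numeric vectors of
#'   couplings of confound / clinical variables on `m` (default 0).
#' @param noise Run-level noise model: `thermal_sd`, `ar1`, `drift_amp`,
#'   `baseline`.
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 18,
                        latent_sd = 1,
                        amplitude_intercept = 2,
                        amplitude_loading = 1.5,
                        amplitude_noise_sd = 1.5 * sqrt(1 / 0.6 - 1),
                        rsn_loadings = c(vnm = 0.45, vnop = 0.4, anr = 0.4,
                                         anl = 0.4, smn1 = 1.0, smn2 = 0.7,
                                         dmn = 0.5, dan = 0.45, ecn = 0.0),
                        rsn_baselines = rep(2, length(rsn_loadings)),
                        rsn_noise_sd = 0.2,
                        tract_md_baselines = rep(1.2, 16),
                        tract_md_loadings = NULL,
                        tract_fa_baselines = rep(0.25, 16),
                        tract_fa_loadings = NULL,
                        tract_mk_baselines = rep(0.8, 16),
                        tract_mk_loadings = NULL,
                        tract_noise_sd = list(md = 0.05, fa = 0.03, mk = 0.05),
                        tract_shared_sd = list(md = 0.12, fa = 0.03, mk = 0.06),
                        confound_couplings = NULL,
                        clinical_couplings = NULL,
                        noise = list(thermal_sd = 1, ar1 = 0.3,
                                     drift_amp = 0.5, baseline = 100),
                        seed = 1L) {
  tl <- tract_labels()
  des <- tl %in% designated_tracts()
  if (is.null(tract_md_loadings)) {
    tract_md_loadings <- ifelse(des, -0.06, -0.025)
  }
  if (is.null(tract_fa_loadings)) tract_fa_loadings <- ifelse(des, 0.012, 0.006)
  if (is.null(tract_mk_loadings)) tract_mk_loadings <- ifelse(des, 0.018, 0.009)
  spec <- list(
    n_subjects = as.integer(n_subjects), latent_sd = latent_sd,
    amplitude_intercept = amplitude_intercept,
    amplitude_loading = amplitude_loading,
    amplitude_noise_sd = amplitude_noise_sd,
    rsn_loadings = rsn_loadings, rsn_baselines = rsn_baselines,
    rsn_noise_sd = rsn_noise_sd,
    tract_md_baselines = tract_md_baselines,
    tract_md_loadings = tract_md_loadings,
    tract_fa_baselines = tract_fa_baselines,
    tract_fa_loadings = tract_fa_loadings,
    tract_mk_baselines = tract_mk_baselines,
    tract_mk_loadings = tract_mk_loadings,
    tract_noise_sd = tract_noise_sd,
    tract_shared_sd = tract_shared_sd,
    confound_couplings = confound_couplings,
    clinical_couplings = clinical_couplings,
    noise = noise, seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (spec$latent_sd <= 0 || spec$amplitude_noise_sd <= 0 ||
      spec$rsn_noise_sd <= 0) {
    stop("all sd parameters must be > 0", call. = FALSE)
  }
  if (length(spec$rsn_loadings) < 1L) stop("need K >= 1 networks", call. = FALSE)
  if (length(spec$rsn_baselines) != length(spec$rsn_loadings)) {
    stop("rsn_baselines and rsn_loadings must have equal length", call. = FALSE)
  }
  for (f in c("tract_md_baselines", "tract_md_loadings", "tract_fa_baselines",
              "tract_fa_loadings", "tract_mk_baselines", "tract_mk_loadings")) {
    if (length(spec[[f]]) != 16L) {
      stop(sprintf("%s must have length 16", f), call. = FALSE)
    }
  }
  invisible(spec)
}

# Default confound scales: task-run (fd, stimulus-correlated motion, csf),
# rest-run (fd, csf, wm), dMRI (motion, noisy voxels, total brain volume).
default_confound_model <- function() {
  tibble::tribble(
    ~name,              ~mean,   ~sd,
    "task_mean_fd",      0.30,    0.10,
    "task_stim_corr",    0.30,    0.08,
    "task_csf_amp",      1.00,    0.25,
    "rest_mean_fd",      0.25,    0.08,
    "rest_csf_amp",      1.20,    0.30,
    "rest_wm_amp",       0.90,    0.20,
    "dmri_motion",       0.40,    0.12,
    "dmri_noisy_vox",  400.0,   120.0,
    "dmri_tbv",     289823.0, 49021.0
  )
}

default_clinical_model <- function() {
  tibble::tribble(
    ~name,  ~mean,     ~sd,
    "ga",    38.3,     1.8,
    "pma",   38.7,     1.7,
    "pna",    2.8,     2.3,
    "bw",     3.34,    0.69,
    "tbv", 289823, 49021
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a cohort from the linear-Gaussian latent model in a [cohort_spec()].
#' Output is bit-reproducible from `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `cohort_truth` with tibbles `subjects` (subject_id,
#'   m, amplitude_true), `rsn` (true network amplitudes), `tracts` (48
#'   tract-parameter features named `<tract>_<param>`), `confounds`,
#'   `clinical`, plus the `spec`.
#' @export
gen_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_subjects
  with_seed(spec$seed, {
    ids <- sprintf("sub-%03d", seq_len(n))
    m <- rnorm(n, 0, spec$latent_sd)
    a <- spec$amplitude_intercept + spec$amplitude_loading * m +
      rnorm(n, 0, spec$amplitude_noise_sd)
    K <- length(spec$rsn_loadings)
    rsn <- sapply(seq_len(K), function(k) {
      spec$rsn_baselines[k] + spec$rsn_loadings[k] * m +
        rnorm(n, 0, spec$rsn_noise_sd)
    })
    colnames(rsn) <- paste0("rsn_", names(spec$rsn_loadings))
    tl <- tract_labels()
    tr <- list()
    for (p in c("md", "fa", "mk")) {
      base <- spec[[paste0("tract_", p, "_baselines")]]
      load <- spec[[paste0("tract_", p, "_loadings")]]
      sdp <- spec$tract_noise_sd[[p]]
      shared_sd <- (spec$tract_shared_sd %||% list())[[p]] %||% 0
      # shared maturation-independent factor drives the strong inter-tract
      # correlation seen in neonatal diffusion data
      g <- rnorm(n, 0, 1)
      mat <- sapply(seq_len(16L), function(t) {
        base[t] + load[t] * m + shared_sd * g + rnorm(n, 0, sdp)
      })
      colnames(mat) <- paste0(tl, "_", p)
      tr[[p]] <- mat
    }
    conf_model <- default_confound_model()
    conf <- sapply(seq_len(nrow(conf_model)), function(i) {
      cp <- 0
      if (!is.null(spec$confound_couplings)) {
        cp <- spec$confound_couplings[[conf_model$name[i]]] %||% 0
      }
      conf_model$mean[i] + cp * m + rnorm(n, 0, conf_model$sd[i])
    })
    colnames(conf) <- conf_model$name
    clin_model <- default_clinical_model()
    clin <- sapply(seq_len(nrow(clin_model)), function(i) {
      cp <- 0
      if (!is.null(spec$clinical_couplings)) {
        cp <- spec$clinical_couplings[[clin_model$name[i]]] %||% 0
      }
      clin_model$mean[i] + cp * m + rnorm(n, 0, clin_model$sd[i])
    })
    colnames(clin) <- clin_model$name
    sex <- stats::rbinom(n, 1, 0.5)
    structure(list(
      subjects = tibble::tibble(subject_id = ids, m = m, amplitude_true = a),
      rsn = tibble::tibble(subject_id = ids, !!!as.data.frame(rsn)),
      tracts = tibble::tibble(subject_id = ids, !!!as.data.frame(tr$md),
                              !!!as.data.frame(tr$fa), !!!as.data.frame(tr$mk)),
      confounds = tibble::tibble(subject_id = ids, !!!as.data.frame(conf)),
      clinical = tibble::tibble(subject_id = ids, !!!as.data.frame(clin),
                                sex = sex),
      spec = spec), class = "cohort_truth")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Smooth standardized random field within the mask (zero outside).
random_field <- function(geometry, fwhm_mm = 8) {
  d <- geometry$grid_shape
  f <- gaussian_smooth_3d(array(rnorm(prod(d)), d), fwhm_mm,
                          geometry$voxel_size_mm)
  v <- f[geometry$mask]
  f[geometry$mask] <- (v - mean(v)) / sd(v)
  f[!geometry$mask] <- 0
  f
}

#' Generate phantom template maps
#'
#' Produces a group evoked-response map, `k_rsn` mutually orthogonal
#' resting-state network maps, and adult template maps whose spatial Pearson
#' correlation with the group map (within the mask) equals the requested
#' targets. All maps are smooth Gaussian random fields, standardized within
#' the mask.
#'
#' @param geometry A [phantom_geometry()].
#' @param k_rsn Number of network maps.
#' @param adult_target_corrs Target spatial correlations in `[-1, 1]`.
#' @param seed Integer seed.
#' @param fwhm_mm Smoothness of the random fields.
#' @return List with `group_map`, `rsn_maps` (named list), `adult_maps`
#'   (list), `mask`, `geometry`.
#' @export
gen_templates <- function(geometry, k_rsn = 9, adult_target_corrs = numeric(),
                          seed = 1L, fwhm_mm = 8) {
  if (any(abs(adult_target_corrs) > 1)) {
    stop("target correlations must lie in [-1, 1]", call. = FALSE)
  }
  with_seed(seed, {
    msk <- geometry$mask
    group <- random_field(geometry, fwhm_mm)
    g <- group[msk]
    # Orthogonalize successive fields (Gram-Schmidt) within the mask so
    # network maps are mutually uncorrelated and uncorrelated with the
    # group map.
    basis <- list(g / sqrt(sum(g^2)))
    mk_orth <- function() {
      f <- random_field(geometry, fwhm_mm)
      v <- f[msk]
      for (b in basis) v <- v - sum(v * b) * b
      v <- v - mean(v)
      for (b in basis) v <- v - sum(v * b) * b
      v <- v / sd(v)
      basis[[length(basis) + 1L]] <<- v / sqrt(sum(v^2))
      f[msk] <- v
      f
    }
    rsn <- lapply(seq_len(k_rsn), function(k) mk_orth())
    names(rsn) <- if (k_rsn == length(rsn_labels())) rsn_labels() else
      paste0("net", seq_len(k_rsn))
    adult <- lapply(adult_target_corrs, function(rho) {
      if (abs(rho) == 1) {
        out <- group
        out[msk] <- rho * g
        return(out)
      }
      e <- random_field(geometry, fwhm_mm)
      v <- e[msk]
      gu <- (g - mean(g)); gu <- gu / sqrt(sum(gu^2))
      v <- v - sum(v * gu) * gu
      v <- v - mean(v)
      v <- v - sum(v * gu) * gu
      v <- v / sd(v)
      out <- group
      out[msk] <- rho * (g - mean(g)) / sd(g) + sqrt(1 - rho^2) * v
      out[!msk] <- 0
      out
    })
    list(group_map = group, rsn_maps = rsn, adult_maps = adult,
         mask = msk, geometry = geometry)
  })
}

#' Default noxious-stimulation event schedule
#'
#' Ten 1 s trials with a minimum 25 s inter-stimulus interval, jittered
#' uniformly, fitting inside the default run length.
#'
#' @param n_events,duration,min_isi,first_onset,jitter_max Schedule
#'   parameters (seconds).
#' @param seed Integer seed for the jitter.
#' @return Tibble with columns `onset`, `duration`.
#' @export
default_event_table <- function(n_events = 10, duration = 1, min_isi = 25,
                                first_onset = 20, jitter_max = 6, seed = 1L) {
  with_seed(seed, {
    gaps <- min_isi + runif(n_events - 1, 0, jitter_max)
    onsets <- first_onset + c(0, cumsum(gaps))
    tibble::tibble(onset = onsets, duration = rep(duration, n_events))
  })
}

# AR(1) coloured noise timeseries of length nt (marginal sd ~ sd_target).
ar1_noise <- function(nt, sd_target, phi) {
  if (sd_target <= 0) return(numeric(nt))
  e <- rnorm(nt, 0, sd_target * sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

#' Generate a synthetic noxious-stimulation task run
#'
#' Signal model: `baseline + a_true * group_map(v) * s(t) + drift + AR(1)
#' noise`, where `s(t)` is the event boxcar convolved with the double-gamma
#' HRF. With all noise parameters zero the data equal the signal component
#' exactly, so the GLM amplitude pipeline recovers `a_true` to machine
#' precision.
#'
#' @param a_true True overall amplitude.
#' @param group_map 3D array (the shared response pattern).
#' @param events Event table (`onset`, `duration` in seconds).
#' @param tr Repetition time (s).
#' @param n_vols Number of volumes.
#' @param noise List with `thermal_sd`, `ar1`, `drift_amp`, `baseline`.
#' @param hrf Sampled haemodynamic kernel.
#' @param mask Logical array; voxels outside are left at zero.
#' @param seed Integer seed.
#' @return 4D array (`x, y, z, t`) with attributes `tr` and `voxel_size`.
#' @export
gen_task_run <- function(a_true, group_map, events, tr = 1.3, n_vols = 277,
                         noise = list(thermal_sd = 1, ar1 = 0.3,
                                      drift_amp = 0.5, baseline = 100),
                         hrf = double_gamma_hrf(), mask = NULL, seed = 1L) {
  if (nrow(events) > 0L && any(events$onset + events$duration > n_vols * tr)) {
    stop("event extends beyond the end of the run", call. = FALSE)
  }
  d <- dim(group_map)
  if (is.null(mask)) mask <- array(TRUE, d)
  s <- convolve_events(events, n_vols, tr, hrf)
  with_seed(seed, {
    nv <- sum(mask)
    g <- group_map[mask]
    sig <- noise$baseline + a_true * outer(g, s)
    if (noise$drift_amp > 0) {
      tt <- seq(-1, 1, length.out = n_vols)
      slopes <- rnorm(nv, 0, noise$drift_amp)
      sig <- sig + outer(slopes, tt)
    }
    if (noise$thermal_sd > 0) {
      eps <- matrix(rnorm(nv * n_vols, 0, noise$thermal_sd *
                            sqrt(1 - noise$ar1^2)), nv, n_vols)
      eps <- t(apply(eps, 1, function(e)
        as.numeric(stats::filter(e, noise$ar1, method = "recursive"))))
      sig <- sig + eps
    }
    out <- array(0, c(d, n_vols))
    flat <- matrix(out, prod(d), n_vols)
    flat[which(mask), ] <- sig
    out <- array(flat, c(d, n_vols))
    attr(out, "tr") <- tr
    attr(out, "voxel_size") <- attr(group_map, "voxel_size") %||% c(2, 2, 2)
    out
  })
}

#' Generate a synthetic resting-state run
#'
#' Data model: `baseline + sum_k map_k(v) z_k(t) + AR(1) noise`, where each
#' network timeseries `z_k` is Gaussian with SD `amplitude_k / 0.6745`, so
#' the population median absolute deviation of `z_k` equals the requested
#' amplitude (Gaussian MAD = 0.6745 sd).
#'
#' @param rsn_amplitudes_true Nonnegative amplitudes, one per map.
#' @param rsn_maps List of 3D arrays.
#' @param tr Repetition time (s).
#' @param n_vols Number of frames.
#' @param noise List with `thermal_sd`, `ar1`, `baseline`.
#' @param mask Logical array.
#' @param seed Integer seed.
#' @return 4D array with attributes `tr`, `voxel_size`, and the generated
#'   network timeseries as attribute `z_true` (K x T).
#' @export
gen_rest_run <- function(rsn_amplitudes_true, rsn_maps, tr = 1.3,
                         n_vols = 500,
                         noise = list(thermal_sd = 1, ar1 = 0.3, baseline = 100),
                         mask = NULL, seed = 1L) {
  K <- length(rsn_maps)
  if (length(rsn_amplitudes_true) != K) {
    stop("need one amplitude per network map", call. = FALSE)
  }
  d <- dim(rsn_maps[[1]])
  if (is.null(mask)) mask <- array(TRUE, d)
  with_seed(seed, {
    gauss_mad <- qnorm(0.75)  # 0.6745
    z <- sapply(seq_len(K), function(k) {
      rnorm(n_vols, 0, rsn_amplitudes_true[k] / gauss_mad)
    })  # T x K
    nv <- sum(mask)
    M <- sapply(rsn_maps, function(mp) mp[mask])  # nv x K
    sig <- noise$baseline + M %*% t(z)
    if (noise$thermal_sd > 0) {
      eps <- matrix(rnorm(nv * n_vols, 0, noise$thermal_sd *
                            sqrt(1 - noise$ar1^2)), nv, n_vols)
      eps <- t(apply(eps, 1, function(e)
        as.numeric(stats::filter(e, noise$ar1, method = "recursive"))))
      sig <- sig + eps
    }
    flat <- matrix(0, prod(d), n_vols)
    flat[which(mask), ] <- sig
    out <- array(flat, c(d, n_vols))
    attr(out, "tr") <- tr
    attr(out, "voxel_size") <- attr(rsn_maps[[1]], "voxel_size") %||% c(2, 2, 2)
    attr(out, "z_true") <- t(z)
    out
  })
}

#' Simulate a rigid-motion parameter table
#'
#' Six rigid-body parameters (3 translations mm, 3 rotations rad) simulated
#' as random walks with AR(1) increments; occasional spikes via a mixture
#' knob.
#'
#' @param n_vols Number of frames.
#' @param step_sd Increment SD (translations mm; rotations scaled by 0.01).
#' @param ar1 AR(1) coefficient of the increments.
#' @param spike_prob Probability a frame's increment is a spike.
#' @param spike_scale Multiplier applied to spike increments.
#' @param seed Integer seed.
#' @return Tibble with columns `trans_x/y/z`, `rot_x/y/z`.
#' @export
gen_motion_table <- function(n_vols = 277, step_sd = 0.02, ar1 = 0.4,
                             spike_prob = 0.01, spike_scale = 10, seed = 1L) {
  with_seed(seed, {
    cols <- lapply(1:6, function(j) {
      scale_j <- if (j <= 3) step_sd else step_sd * 0.01
      inc <- ar1_noise(n_vols, scale_j, ar1)
      spikes <- runif(n_vols) < spike_prob
      inc[spikes] <- inc[spikes] * spike_scale
      cumsum(inc)
    })
    names(cols) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    tibble::as_tibble(cols)
  })
}

#' Write a synthetic dataset to disk
#'
#' Lays out NIfTI maps/runs and TSV tables under `out_dir` and returns a
#' manifest tibble (also written as `manifest.json`) listing every file with
#' its MD5 checksum.
#'
#' @param cohort A `cohort_truth`.
#' @param templates Output of [gen_templates()].
#' @param runs Optional named list of 4D arrays to write (e.g. task/rest
#'   runs keyed by file stem).
#' @param out_dir Output directory (created if needed).
#' @return Tibble with columns `file`, `md5`.
#' @export
write_dataset <- function(cohort, templates, runs = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wv <- function(x, name) {
    p <- file.path(out_dir, name)
    write_volume(x, p)
    files <<- c(files, p)
  }
  wt <- function(tab, name) {
    p <- file.path(out_dir, name)
    write_table(tab, p)
    files <<- c(files, p)
  }
  wv(templates$group_map, "group_map.nii.gz")
  for (k in seq_along(templates$rsn_maps)) {
    wv(templates$rsn_maps[[k]],
       sprintf("rsn_%s.nii.gz", names(templates$rsn_maps)[k]))
  }
  for (k in seq_along(templates$adult_maps)) {
    wv(templates$adult_maps[[k]], sprintf("adult_template_%02d.nii.gz", k))
  }
  wv(array(as.numeric(templates$mask), dim(templates$group_map)), "mask.nii.gz")
  wt(cohort$subjects, "subjects.tsv")
  wt(cohort$rsn, "rsn_true.tsv")
  wt(cohort$tracts, "tract_features.tsv")
  wt(cohort$confounds, "confounds.tsv")
  wt(cohort$clinical, "clinical.tsv")
  if (!is.null(runs)) {
    for (nm in names(runs)) wv(runs[[nm]], paste0(nm, ".nii.gz"))
  }
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
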