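#' Quality-control thresholding of a diffusion parameter map
#'
#' Removes voxels with values outside the expected theoretical range of the
#' parameter (negative MD; FA outside `[0, 1]`; MK outside `[0, 3]`),
#' typically noise from poor SNR or head motion. Removed voxels are set to
#' `NA` so downstream tract means skip them.
#'
#' @param param_map 3D array.
#' @param kind `"MD"`, `"FA"` or `"MK"`.
#' @return List with `map` (cleaned array, removed voxels `NA`) and
#'   `removed` (count of removed voxels).
#' @export
qc_threshold_map <- function(param_map, kind = c("MD", "FA", "MK")) {
  kind <- match.arg(kind)
  rng <- switch(kind, MD = c(0, Inf), FA = c(0, 1), MK = c(0, 3))
  bad <- !is.na(param_map) & (param_map < rng[1] | param_map > rng[2])
  out <- param_map
  out[bad] <- NA_real_
  list(map = out, removed = sum(bad))
}

#' Tract-mean diffusion parameter
#'
#' Arithmetic mean of a parameter map over voxels whose group-averaged
#' tract probability is at least `prob_threshold` (default 0.01) and that
#' survived QC (non-`NA`).
#'
#' @param param_map 3D array (QC'd: out-of-range voxels `NA`).
#' @param tract_prob_map 3D array of tract probabilities.
#' @param prob_threshold Probability threshold (default 0.01).
#' @return Scalar mean.
#' @export
tract_mean <- function(param_map, tract_prob_map, prob_threshold = 0.01) {
  sel <- tract_prob_map >= prob_threshold & !is.na(param_map)
  if (!any(sel)) stop("tract mask is empty after thresholding/QC", call. = FALSE)
  mean(param_map[sel])
}

#' Confound-adjusted Pearson correlation
#'
#' Pearson correlation of the OLS residuals of `x` and `y` each regressed
#' on the confound matrix `Z` plus an intercept (partial correlation given
#' `Z`). With `Z = NULL` this is the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param Z Confound matrix (n x q) or NULL.
#' @return Scalar correlation.
#' @export
adjusted_correlation <- function(x, y, Z = NULL) {
  n <- length(x)
  idx <- seq_len(n)
  rx <- as.numeric(residualize_on(matrix(x), Z, idx))
  ry <- as.numeric(residualize_on(matrix(y), Z, idx))
  # relative threshold: residuals that are numerically zero mean the
  # confounds span the input
  if (sd(rx) <= 1e-10 * max(sd(x), 1e-300) ||
      sd(ry) <= 1e-10 * max(sd(y), 1e-300)) {
    stop("zero-variance residual: confound collinear with input", call. = FALSE)
  }
  cor(rx, ry)
}

# Parse "<tract>_<param>" feature names into a tract/parameter tibble.
parse_feature_names <- function(nm) {
  parts <- strsplit(nm, "_(?=[^_]+$)", perl = TRUE)
  tibble::tibble(tract = vapply(parts, `[`, "", 1),
                 parameter = toupper(vapply(parts, `[`, "", 2)))
}

# Residualize a matrix on Z and standardize columns to unit sample sd.
resid_std <- function(A, Z) {
  R <- residualize_on(as.matrix(A), Z, seq_len(nrow(as.matrix(A))))
  s <- apply(R, 2, sd)
  if (any(s == 0)) stop("zero-variance residual column", call. = FALSE)
  sweep(R, 2, s, `/`)
}

#' Exploratory structure-function screen with max-statistic FWER control
#'
#' Confound-adjusted Pearson correlations between response amplitudes and
#' every tract-parameter feature, with single-step max-|r| permutation
#' family-wise error control (Westfall-Young style): each permutation
#' shuffles the amplitude vector, recomputes all adjusted correlations and
#' records the maximum |r|; a feature's FWER p is the proportion of
#' permutations whose maximum reaches its observed |r|.
#'
#' @param amplitudes Length-n response vector.
#' @param features n x m feature matrix or tibble (columns named
#'   `<tract>_<param>`).
#' @param confounds Confound matrix (e.g. dMRI motion, noisy-voxel count,
#'   total brain volume) or NULL.
#' @param alpha Family-wise alpha for significance flags.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Object of class `nox_screen`: tibble with columns `tract`,
#'   `parameter`, `r`, `p`, `fwer_p`, `significant`, plus permutation
#'   metadata.
#' @export
exploratory_screen <- function(amplitudes, features, confounds = NULL,
                               alpha = 0.05, n_perm = 1000, seed = 1L) {
  Fm <- as.matrix(dplyr::select(tibble::as_tibble(features),
                                -dplyr::any_of("subject_id")))
  storage.mode(Fm) <- "double"
  n <- nrow(Fm)
  if (length(amplitudes) != n) stop("length mismatch", call. = FALSE)
  if (n < 10L) stop("need at least 10 subjects", call. = FALSE)
  if (anyNA(Fm) || anyNA(amplitudes)) stop("table is incomplete", call. = FALSE)
  Fs <- resid_std(Fm, confounds)
  ys <- as.numeric(resid_std(matrix(amplitudes), confounds))
  r_obs <- as.numeric(crossprod(Fs, ys)) / (n - 1)
  perm_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yb <- as.numeric(resid_std(matrix(sample(amplitudes)), confounds))
      as.numeric(crossprod(Fs, yb)) / (n - 1)
    }, numeric(ncol(Fs)))
  })  # m x B
  eps <- 1e-12
  max_abs <- apply(abs(perm_r), 2, max)
  p_unadj <- (1 + rowSums(abs(perm_r) >= abs(r_obs) - eps)) / (1 + n_perm)
  p_fwer <- vapply(abs(r_obs), function(a) (1 + sum(max_abs >= a - eps)) /
                     (1 + n_perm), numeric(1))
  info <- parse_feature_names(colnames(Fm))
  res <- tibble::tibble(
    tract = info$tract, parameter = info$parameter,
    r = r_obs, p = p_unadj, fwer_p = p_fwer,
    significant = p_fwer <= alpha)
  structure(list(results = res, alpha = alpha, n_perm = n_perm, seed = seed,
                 null_max_abs_r = max_abs),
            class = "nox_screen")
}

#' First principal component of tract-mean diffusivity
#'
#' PCA of a subjects-by-tracts matrix (column-standardized by default, so
#' tracts contribute equally regardless of level and spread). The PC1 sign
#' is fixed so the mean loading is positive: higher scores mean higher
#' diffusivity, keeping the hypothesised correlation sign well defined.
#'
#' @param values n x k numeric matrix.
#' @param standardize Column-standardize before PCA (default TRUE).
#' @return List with `scores` (length n), `variance_fraction` (of PC1),
#'   `loadings` (length k).
#' @export
md_pc1 <- function(values, standardize = TRUE) {
  V <- as.matrix(values)
  if (nrow(V) < 2L || ncol(V) < 1L) stop("need >= 2 subjects, >= 1 tract", call. = FALSE)
  s <- apply(V, 2, sd)
  if (standardize && any(s == 0)) {
    stop("zero-variance column cannot be standardized", call. = FALSE)
  }
  Vc <- sweep(V, 2, colMeans(V))
  if (standardize) Vc <- sweep(Vc, 2, s, `/`)
  C <- crossprod(Vc) / (nrow(V) - 1)
  eg <- eigen(C, symmetric = TRUE)
  v1 <- eg$vectors[, 1]
  if (mean(v1) < 0) v1 <- -v1
  list(scores = as.numeric(Vc %*% v1),
       variance_fraction = eg$values[1] / sum(eg$values),
       loadings = v1)
}

#' Confirmatory directional test of the tract-subset association
#'
#' Tests the data-driven hypotheses formed in the exploratory arm: reports
#' the per-tract adjusted correlation polarities, pools the subset's
#' diffusivity with PC1 (on confound-residualized values by default), and
#' tests the PC1-amplitude adjusted correlation one-tailed in the
#' hypothesised direction by permutation.
#'
#' @param amplitudes Length-n response vector.
#' @param md_subset n x k matrix of tract-mean MD for the hypothesised
#'   subset.
#' @param confounds Confound matrix or NULL.
#' @param direction `"negative"` (default) or `"positive"` hypothesised
#'   correlation.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param residualize_first Compute the PCA on confound-residualized tract
#'   values (default TRUE); otherwise raw values.
#' @param standardize Column-standardize before PCA.
#' @return Object of class `nox_confirmatory`: `polarity` tibble (`tract`,
#'   `r`, `sign`), `pc1_r`, `p`, `variance_fraction`, metadata.
#' @export
confirmatory_test <- function(amplitudes, md_subset, confounds = NULL,
                              direction = c("negative", "positive"),
                              n_perm = 1000, seed = 1L,
                              residualize_first = TRUE, standardize = TRUE) {
  direction <- match.arg(direction)
  M <- as.matrix(md_subset)
  n <- nrow(M)
  if (n < 5L) stop("need at least 5 subjects", call. = FALSE)
  if (length(amplitudes) != n) stop("length mismatch", call. = FALSE)
  r_tract <- vapply(seq_len(ncol(M)), function(j)
    adjusted_correlation(M[, j], amplitudes, confounds), numeric(1))
  nm <- colnames(M) %||% paste0("tract", seq_len(ncol(M)))
  pca_input <- if (residualize_first) {
    residualize_on(M, confounds, seq_len(n))
  } else M
  pc <- md_pc1(pca_input, standardize = standardize)
  r_obs <- adjusted_correlation(pc$scores, amplitudes, confounds)
  null_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b)
      adjusted_correlation(pc$scores, sample(amplitudes), confounds),
      numeric(1))
  })
  eps <- 1e-12
  cnt <- if (direction == "negative") sum(null_r <= r_obs + eps) else
    sum(null_r >= r_obs - eps)
  p <- (1 + cnt) / (1 + n_perm)
  structure(list(
    polarity = tibble::tibble(tract = nm, r = r_tract,
                              sign = ifelse(r_tract < 0, "negative", "positive")),
    pc1_r = r_obs, p = p, variance_fraction = pc$variance_fraction,
    direction = direction, n_perm = n_perm, seed = seed, null = null_r),
    class = "nox_confirmatory")
}

#' All-subsets tract combination analysis
#'
#' For every nonempty subset of the tract universe (65,535 subsets for 16
#' tracts), computes the squared adjusted correlation between the subset's
#' diffusivity PC1 and the response amplitudes, and locates the target
#' subset's r^2 in that distribution as an inclusive percentile
#' (`100 * #\{subsets with r^2 <= target\} / total`).
#'
#' @param amplitudes Length-n response vector.
#' @param md_table n x k matrix of tract-mean MD (columns named by tract).
#' @param confounds Confound matrix or NULL.
#' @param target_subset Character vector of tract names (or integer
#'   indices) forming the hypothesised subset.
#' @param standardize Column-standardize before PCA.
#' @return Object of class `nox_subsets`: tibble `subsets` (`bitmask`,
#'   `size`, `r2`), `target_r2`, `percentile`.
#' @export
subset_combination_analysis <- function(amplitudes, md_table, confounds = NULL,
                                        target_subset, standardize = TRUE) {
  M <- as.matrix(md_table)
  k <- ncol(M)
  nm <- colnames(M) %||% paste0("tract", seq_len(k))
  if (is.character(target_subset)) {
    target_idx <- match(target_subset, nm)
    if (anyNA(target_idx)) stop("unknown tract in target_subset", call. = FALSE)
  } else target_idx <- as.integer(target_subset)
  if (length(target_idx) == 0L) stop("target subset is empty", call. = FALSE)
  n <- nrow(M)
  Rm <- residualize_on(M, confounds, seq_len(n))
  if (standardize) {
    s <- apply(Rm, 2, sd)
    if (any(s == 0)) stop("zero-variance residual column", call. = FALSE)
    Rm <- sweep(Rm, 2, s, `/`)
  }
  ys <- as.numeric(residualize_on(matrix(amplitudes), confounds, seq_len(n)))
  ys <- ys / sd(ys)
  C <- crossprod(Rm) / (n - 1)
  cvec <- as.numeric(crossprod(Rm, ys)) / (n - 1)
  n_sub <- 2^k - 1
  r2 <- numeric(n_sub)
  size <- integer(n_sub)
  for (bm in seq_len(n_sub)) {
    S <- which(bitwAnd(bm, bitwShiftL(1L, 0:(k - 1L))) > 0L)
    size[bm] <- length(S)
    if (length(S) == 1L) {
      r2[bm] <- cvec[S]^2 / C[S, S]
    } else {
      eg <- eigen(C[S, S], symmetric = TRUE)
      v1 <- eg$vectors[, 1]
      r2[bm] <- sum(v1 * cvec[S])^2 / eg$values[1]
    }
  }
  target_bm <- sum(bitwShiftL(1L, target_idx - 1L))
  target_r2 <- r2[target_bm]
  structure(list(
    subsets = tibble::tibble(bitmask = seq_len(n_sub), size = size, r2 = r2),
    target_r2 = target_r2,
    percentile = 100 * sum(r2 <= target_r2 + 1e-12) / n_sub,
    tracts = nm, target_subset = nm[target_idx]),
    class = "nox_subsets")
}

#' Cross-dataset similarity of tract correlation profiles
#'
#' Pearson correlation between two per-tract correlation profiles (one per
#' dataset), quantifying how consistently tract-to-tract variability in
#' structure-function association strength reproduces across datasets.
#'
#' @param r_a,r_b Equal-length (>= 3) numeric vectors of per-tract
#'   correlations.
#' @return Scalar Pearson correlation.
#' @export
compare_tract_profiles <- function(r_a, r_b) {
  if (length(r_a) != length(r_b)) stop("length mismatch", call. = FALSE)
  if (length(r_a) < 3L) stop("need at least 3 tracts", call. = FALSE)
  if (sd(r_a) == 0 || sd(r_b) == 0) stop("constant profile", call. = FALSE)
  cor(r_a, r_b)
}

#' @export
print.nox_screen <- function(x, ...) {
  cat(sprintf("Exploratory screen: %d tests, %d permutations, alpha = %g\n",
              nrow(x$results), x$n_perm, x$alpha))
  print(dplyr::arrange(x$results, .data$fwer_p))
  invisible(x)
}

#' @export
tidy.nox_screen <- function(x, ...) x$results

#' @export
glance.nox_screen <- function(x, ...) {
  tibble::tibble(n_tests = nrow(x$results),
                 n_significant = sum(x$results$significant),
                 alpha = x$alpha, n_perm = x$n_perm)
}

#' @export
print.nox_confirmatory <- function(x, ...) {
  cat(sprintf("Confirmatory %s-tailed test: PC1 r = %.3f, p = %.4g (PC1 variance fraction %.1f%%)\n",
              x$direction, x$pc1_r, x$p, 100 * x$variance_fraction))
  print(x$polarity)
  invisible(x)
}

#' @export
tidy.nox_confirmatory <- function(x, ...) x$polarity

#' @export
glance.nox_confirmatory <- function(x, ...) {
  tibble::tibble(pc1_r = x$pc1_r, p.value = x$p,
                 variance_fraction = x$variance_fraction,
                 direction = x$direction, n_perm = x$n_perm)
}

#' @export
tidy.nox_subsets <- function(x, ...) x$subsets

#' @export
glance.nox_subsets <- function(x, ...) {
  tibble::tibble(n_subsets = nrow(x$subsets), target_r2 = x$target_r2,
                 percentile = x$percentile)
}

#' Plot the exploratory screen correlation profile
#'
#' Horizontal bar chart of adjusted correlations per tract, faceted by
#' diffusion parameter, with FWER-significant associations highlighted.
#'
#' @param object A `nox_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nox_screen <- function(object, ...) {
  res <- object$results
  ord <- res[res$parameter == "MD", ]
  lev <- ord$tract[order(ord$r)]
  res$tract <- factor(res$tract, levels = lev)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$r, y = .data$tract,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~.data$parameter) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "#b2182b")) +
    ggplot2::labs(x = "adjusted Pearson r", y = NULL,
                  fill = "FWER-significant") +
    ggplot2::theme_minimal()
}
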