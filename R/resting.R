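#' Network timeseries by spatial multiple regression
#'
#' Stage-1 dual regression: for every frame, the in-mask voxel vector is
#' regressed on the K template maps plus an intercept; the K regression
#' coefficients form that frame's network values. The per-frame intercept
#' absorbs the global signal level so it does not leak into network
#' coefficients.
#'
#' @param bold 4D array (`x, y, z, t`).
#' @param templates List of 3D template maps, linearly independent within
#'   the mask.
#' @param mask Logical 3D array.
#' @return List of class `network_timeseries`: `series` (K x T matrix),
#'   `labels`, `tr`.
#' @export
spatial_regression_timeseries <- function(bold, templates, mask = NULL) {
  d <- dim(bold)
  if (length(d) != 4L) stop("`bold` must be a 4D array", call. = FALSE)
  if (length(templates) < 1L) stop("need at least one template", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  X <- cbind(intercept = 1, sapply(templates, function(m) m[mask]))
  if (qr(X)$rank < ncol(X)) {
    stop("templates are collinear within the mask", call. = FALSE)
  }
  Y <- matrix(bold, prod(d[1:3]), d[4])[which(mask), , drop = FALSE]  # v x t
  B <- qr.coef(qr(X), Y)  # (K+1) x t
  series <- B[-1, , drop = FALSE]
  labels <- names(templates)
  if (is.null(labels)) labels <- paste0("net", seq_along(templates))
  rownames(series) <- labels
  structure(list(series = series, labels = labels,
                 tr = attr(bold, "tr") %||% NA_real_),
            class = "network_timeseries")
}

#' Median absolute deviation amplitude
#'
#' Timeseries amplitude as the median absolute deviation from the median,
#' unscaled by default (`constant = 1`); the Gaussian consistency constant
#' 1.4826 can be supplied to put amplitudes on the SD scale.
#'
#' @param series Numeric vector (length >= 2).
#' @param constant Scale factor (default 1, i.e. raw MAD).
#' @return Scalar amplitude.
#' @export
mad_amplitude <- function(series, constant = 1) {
  if (length(series) < 2L) stop("need at least two frames", call. = FALSE)
  constant * median(abs(series - median(series)))
}

#' Fraction of outlying frames in a timeseries
#'
#' Frames with `|x - median| > k * MAD` count as outliers; if the MAD is
#' zero the rule falls back to `k * sd`, and if both are zero the fraction
#' is 0.
#'
#' @param series Numeric vector (length >= 2).
#' @param k Threshold multiplier (default 5).
#' @return Fraction in `[0, 1]`.
#' @export
outlier_fraction <- function(series, k = 5) {
  if (length(series) < 2L) stop("need at least two frames", call. = FALSE)
  med <- median(series)
  scale <- mad_amplitude(series)
  if (scale == 0) scale <- sd(series)
  if (scale == 0) return(0)
  mean(abs(series - med) > k * scale)
}

#' Match two template sets by spatial correlation
#'
#' Greedy one-to-one assignment: pairs are accepted in descending absolute
#' spatial Pearson correlation; pairs below `min_abs_r` are left unmatched.
#' Mirrors cross-dataset network matching by spatial correlation with an
#' explicit numeric guard in place of visual confirmation.
#'
#' @param set_a,set_b Lists of 3D maps (nonconstant within the mask).
#' @param mask Logical 3D array.
#' @param min_abs_r Minimum `|r|` for an accepted pair (default 0.3).
#' @return Tibble with columns `a`, `b` (indices or names), `r`; one row per
#'   accepted pair.
#' @export
match_templates <- function(set_a, set_b, mask = NULL, min_abs_r = 0.3) {
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("template sets must be nonempty", call. = FALSE)
  }
  if (is.null(mask)) mask <- array(TRUE, dim(set_a[[1]]))
  A <- sapply(set_a, function(m) m[mask])
  Bm <- sapply(set_b, function(m) m[mask])
  if (any(apply(A, 2, sd) == 0) || any(apply(Bm, 2, sd) == 0)) {
    stop("constant map in template set", call. = FALSE)
  }
  R <- cor(A, Bm)  # |a| x |b|
  nm_a <- names(set_a) %||% as.character(seq_along(set_a))
  nm_b <- names(set_b) %||% as.character(seq_along(set_b))
  pairs <- tibble::tibble(a = character(), b = character(), r = numeric())
  free_a <- seq_along(set_a)
  free_b <- seq_along(set_b)
  while (length(free_a) > 0L && length(free_b) > 0L) {
    sub <- abs(R[free_a, free_b, drop = FALSE])
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    ia <- free_a[best[1]]; ib <- free_b[best[2]]
    if (abs(R[ia, ib]) < min_abs_r) break
    pairs <- dplyr::bind_rows(pairs, tibble::tibble(
      a = nm_a[ia], b = nm_b[ib], r = R[ia, ib]))
    free_a <- setdiff(free_a, ia)
    free_b <- setdiff(free_b, ib)
  }
  pairs
}

#' Summarise network amplitudes for a resting run
#'
#' Convenience wrapper: extracts network timeseries by spatial regression
#' and returns one row per network with its MAD amplitude and outlier
#' fraction.
#'
#' @inheritParams spatial_regression_timeseries
#' @param k Outlier threshold multiplier.
#' @return Tibble with columns `network`, `mad`, `outlier_fraction`.
#' @export
rsn_amplitudes <- function(bold, templates, mask = NULL, k = 5) {
  ts <- spatial_regression_timeseries(bold, templates, mask)
  tibble::tibble(
    network = ts$labels,
    mad = unname(apply(ts$series, 1, mad_amplitude)),
    outlier_fraction = unname(apply(ts$series, 1, outlier_fraction, k = k)))
}
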