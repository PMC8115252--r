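#' Framewise displacement from rigid-motion parameters
#'
#' Sum of absolute backward differences of the six rigid-body parameters,
#' with rotations converted to arc length on a sphere (default radius
#' 50 mm). The first frame's FD is 0; the mean is taken over frames 2..T.
#'
#' @param motion T x 6 matrix or data frame: three translations (mm) then
#'   three rotations (rad).
#' @param radius_mm Sphere radius for rotation-to-arc-length conversion.
#' @return List with `fd` (length-T vector) and `mean_fd`.
#' @export
framewise_displacement <- function(motion, radius_mm = 50) {
  m <- as.matrix(motion)
  if (ncol(m) != 6L || nrow(m) < 2L || !is.numeric(m)) {
    stop("motion must be a numeric T x 6 table with T >= 2", call. = FALSE)
  }
  dm <- abs(diff(m))
  fd <- c(0, rowSums(dm[, 1:3, drop = FALSE]) +
            radius_mm * rowSums(dm[, 4:6, drop = FALSE]))
  list(fd = fd, mean_fd = mean(fd[-1]))
}

#' Expand six motion parameters to the 24-regressor set
#'
#' Columns 1-6 are the parameters, 7-12 their backward-difference
#' derivatives (first row 0), and 13-24 the squares of both.
#'
#' @param motion T x 6 numeric matrix or data frame (T >= 3).
#' @return T x 24 matrix.
#' @export
motion_expansion <- function(motion) {
  m <- as.matrix(motion)
  if (ncol(m) != 6L || nrow(m) < 3L) {
    stop("motion must be a T x 6 table with T >= 3", call. = FALSE)
  }
  dm <- rbind(0, diff(m))
  out <- cbind(m, dm, m^2, dm^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("d", 1:6),
                     paste0("p", 1:6, "_sq"), paste0("d", 1:6, "_sq"))
  out
}

#' Stimulus-correlated head motion
#'
#' Multiple correlation coefficient `R = sqrt(R^2)` from the OLS regression
#' of the predicted BOLD response (stimulus timeseries convolved with the
#' HRF) on the 24 motion regressors plus an intercept.
#'
#' @param predicted_response Length-T numeric vector, nonconstant.
#' @param motion24 T x k motion regressor matrix (typically
#'   [motion_expansion()] output).
#' @return Scalar in `[0, 1]`.
#' @export
stimulus_correlated_motion <- function(predicted_response, motion24) {
  y <- as.numeric(predicted_response)
  X <- as.matrix(motion24)
  if (nrow(X) != length(y)) stop("row mismatch", call. = FALSE)
  if (sd(y) == 0) stop("predicted response is constant", call. = FALSE)
  fit <- lm.fit(cbind(1, X), y)
  ssres <- sum(fit$residuals^2)
  sstot <- sum((y - mean(y))^2)
  sqrt(max(0, min(1, 1 - ssres / sstot)))
}

#' ROI amplitude from a beta map or a 4D run
#'
#' `mean_beta`: mean of a 3D regression-coefficient map over ROI voxels
#' (e.g. CSF signal amplitude of the task run). `mad_timeseries`: MAD of the
#' ROI-mean timeseries of a 4D run (e.g. CSF or white-matter amplitude of
#' the resting run).
#'
#' @param source 3D array (`mean_beta`) or 4D array (`mad_timeseries`).
#' @param roi_mask Logical 3D array, nonempty.
#' @param mode `"mean_beta"` or `"mad_timeseries"`.
#' @return Scalar amplitude.
#' @export
roi_amplitude <- function(source, roi_mask, mode = c("mean_beta", "mad_timeseries")) {
  mode <- match.arg(mode)
  if (!any(roi_mask)) stop("ROI is empty", call. = FALSE)
  if (mode == "mean_beta") {
    if (length(dim(source)) != 3L) stop("mean_beta mode needs a 3D map", call. = FALSE)
    mean(source[roi_mask])
  } else {
    d <- dim(source)
    if (length(d) != 4L) stop("mad_timeseries mode needs a 4D run", call. = FALSE)
    Y <- matrix(source, prod(d[1:3]), d[4])[which(roi_mask), , drop = FALSE]
    mad_amplitude(colMeans(Y))
  }
}
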