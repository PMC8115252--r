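#' Double-gamma haemodynamic response function
#'
#' Canonical haemodynamic impulse response: a gamma-density peak minus a
#' scaled gamma-density undershoot, normalised so the kernel maximum is 1.
#' Defaults are the adult canonical parameters (peak shape 6 / scale 1 s,
#' undershoot shape 16 / scale 1 s, undershoot ratio 1/6); all five are
#' configurable so a term-neonate variant can be supplied.
#'
#' @param peak_shape,peak_scale Gamma shape/scale of the positive peak.
#' @param undershoot_shape,undershoot_scale Gamma shape/scale of the
#'   undershoot.
#' @param undershoot_ratio Nonnegative weight of the undershoot component.
#' @param dt Sampling interval in seconds.
#' @param duration Kernel length in seconds.
#' @param amplitude Peak value of the returned kernel (default 1).
#' @return Numeric vector sampled at `t = 0, dt, 2 dt, ...` with attribute
#'   `times`; value at `t = 0` is 0.
#' @examples
#' h <- double_gamma_hrf(dt = 0.1)
#' attr(h, "times")[which.max(h)]  # ~5 s peak latency
#' @export
double_gamma_hrf <- function(peak_shape = 6, peak_scale = 1,
                             undershoot_shape = 16, undershoot_scale = 1,
                             undershoot_ratio = 1 / 6,
                             dt = 0.1, duration = 32, amplitude = 1) {
  if (peak_shape <= 0 || peak_scale <= 0 || undershoot_shape <= 0 ||
      undershoot_scale <= 0) {
    stop("gamma shape and scale parameters must be positive", call. = FALSE)
  }
  if (undershoot_ratio < 0) stop("undershoot_ratio must be >= 0", call. = FALSE)
  if (dt <= 0 || duration <= dt) stop("need dt > 0 and duration > dt", call. = FALSE)
  t <- seq(0, duration, by = dt)
  k <- dgamma(t, shape = peak_shape, scale = peak_scale) -
    undershoot_ratio * dgamma(t, shape = undershoot_shape, scale = undershoot_scale)
  pk <- max(k)
  if (pk <= 0) stop("kernel has non-positive maximum; check parameters", call. = FALSE)
  k <- amplitude * k / pk
  attr(k, "times") <- t
  attr(k, "dt") <- dt
  k
}

#' Build a GLM design matrix for an event-related run
#'
#' Column 1 is the stimulus regressor: a boxcar built from the event table on
#' a fine time grid, convolved with the haemodynamic kernel, then sampled at
#' volume acquisition times. Remaining columns are an intercept and demeaned
#' polynomial drift terms up to `drift_order`.
#'
#' @param events Data frame with numeric columns `onset`, `duration`
#'   (seconds).
#' @param n_vols Number of volumes.
#' @param tr Repetition time (s).
#' @param hrf Sampled kernel from [double_gamma_hrf()] (its `dt` attribute
#'   sets the fine grid).
#' @param drift_order Polynomial drift order (default 1 = linear).
#' @return `n_vols x (2 + drift_order)` design matrix with column names
#'   `stimulus`, `intercept`, `drift1`, ...
#' @export
build_design <- function(events, n_vols, tr, hrf = double_gamma_hrf(),
                         drift_order = 1) {
  if (n_vols < 2L) stop("run is empty or too short", call. = FALSE)
  if (nrow(events) > 0L) {
    if (any(events$duration < 0)) stop("negative event duration", call. = FALSE)
    if (any(events$onset < 0)) stop("negative event onset", call. = FALSE)
    if (any(events$onset + events$duration > n_vols * tr)) {
      stop("event extends beyond the end of the run", call. = FALSE)
    }
  }
  stim <- convolve_events(events, n_vols, tr, hrf)
  tt <- (seq_len(n_vols) - 1) * tr
  X <- cbind(stimulus = stim, intercept = rep(1, n_vols))
  if (drift_order >= 1L) {
    for (d in seq_len(drift_order)) {
      col <- ((tt - mean(tt)) / (max(tt) - min(tt)))^d
      X <- cbind(X, col - mean(col))
    }
    colnames(X) <- c("stimulus", "intercept", paste0("drift", seq_len(drift_order)))
  }
  X
}

# Fine-grid boxcar convolution with the HRF, sampled at volume times.
convolve_events <- function(events, n_vols, tr, hrf) {
  dt <- attr(hrf, "dt")
  run_dur <- n_vols * tr
  n_fine <- ceiling(run_dur / dt) + length(hrf)
  box <- numeric(n_fine)
  if (nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      i0 <- floor(events$onset[i] / dt) + 1L
      i1 <- max(i0, ceiling((events$onset[i] + events$duration[i]) / dt))
      box[i0:min(i1, n_fine)] <- 1
    }
  }
  conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n_fine)] * dt
  vol_idx <- pmin(n_fine, floor((seq_len(n_vols) - 1) * tr / dt) + 1L)
  conv[vol_idx]
}
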