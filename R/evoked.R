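#' Voxelwise ordinary least squares GLM
#'
#' Fits the design to every in-mask voxel's timeseries by OLS and returns
#' per-regressor beta maps, a residual variance map, a per-voxel R^2
#' goodness-of-fit map and the residual degrees of freedom.
#'
#' @param bold 4D array (`x, y, z, t`).
#' @param design `n_vols x p` full-column-rank design matrix.
#' @param mask Logical 3D array (default: all voxels).
#' @return List of class `glm_result` with `betas` (named list of 3D
#'   arrays), `resid_var`, `r_squared`, `df`, `mask`.
#' @export
glm_fit <- function(bold, design, mask = NULL) {
  d <- dim(bold)
  if (length(d) != 4L) stop("`bold` must be a 4D array", call. = FALSE)
  if (nrow(design) != d[4]) stop("design rows must equal n_vols", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  Y <- t(matrix(bold, prod(d[1:3]), d[4])[which(mask), , drop = FALSE])  # t x v
  B <- qr.coef(qrX, Y)                       # p x v
  fit <- design %*% B
  res <- Y - fit
  df <- d[4] - ncol(design)
  sstot <- colSums(sweep(Y, 2, colMeans(Y))^2)
  ssres <- colSums(res^2)
  r2 <- ifelse(sstot > 0, 1 - ssres / sstot, 0)
  r2 <- pmin(pmax(r2, 0), 1)
  to_map <- function(v) {
    m <- array(0, d[1:3]); m[mask] <- v; m
  }
  cn <- colnames(design)
  if (is.null(cn)) cn <- paste0("x", seq_len(ncol(design)))
  betas <- lapply(seq_len(ncol(design)), function(j) to_map(B[j, ]))
  names(betas) <- cn
  structure(list(betas = betas, resid_var = to_map(ssres / df),
                 r_squared = to_map(r2), df = df, mask = mask),
            class = "glm_result")
}

#' One-sample group t-statistic map
#'
#' Per voxel `t = mean / (sd / sqrt(n))` across subject maps (sample sd,
#' n - 1 denominator). Voxels with zero variance get `t = 0` with a warning.
#'
#' @param beta_maps List (length >= 2) of 3D arrays on a common grid.
#' @param mask Logical 3D array.
#' @return 3D array of t statistics.
#' @export
group_tmap <- function(beta_maps, mask = NULL) {
  n <- length(beta_maps)
  if (n < 2L) stop("need at least two subject maps", call. = FALSE)
  d <- dim(beta_maps[[1]])
  if (is.null(mask)) mask <- array(TRUE, d)
  M <- vapply(beta_maps, function(m) m[mask], numeric(sum(mask)))  # v x n
  if (is.null(dim(M))) M <- matrix(M, nrow = 1)
  mu <- rowMeans(M)
  s <- apply(M, 1, sd)
  t <- numeric(length(mu))
  nz <- s > 0
  t[nz] <- mu[nz] / (s[nz] / sqrt(n))
  if (any(!nz)) warning("zero-variance voxels set to t = 0")
  out <- array(0, d)
  out[mask] <- t
  out
}

#' Overall response amplitude by spatial regression
#'
#' Regresses the subject-level response map on the group-level response map
#' (with intercept) over in-mask voxels and returns the slope: the subject's
#' overall evoked-response amplitude relative to the group response.
#'
#' @param subject_map,group_map 3D arrays.
#' @param mask Logical 3D array.
#' @return Scalar regression slope.
#' @export
overall_amplitude <- function(subject_map, group_map, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(group_map))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  g <- group_map[mask]
  s <- subject_map[mask]
  vg <- var(g)
  if (vg == 0) stop("group map is constant within the mask", call. = FALSE)
  cov(g, s) / vg
}

#' Template expression of a subject map
#'
#' Pearson spatial correlation (demeaned) or cosine similarity (no
#' demeaning, so magnitude information is retained) between a subject map
#' and a template over in-mask voxels.
#'
#' @param subject_map,template 3D arrays.
#' @param mask Logical 3D array.
#' @param method `"pearson"` or `"cosine"`.
#' @return Scalar similarity.
#' @export
template_expression <- function(subject_map, template, mask = NULL,
                                method = c("pearson", "cosine")) {
  method <- match.arg(method)
  if (is.null(mask)) mask <- array(TRUE, dim(template))
  s <- subject_map[mask]
  t <- template[mask]
  if (method == "pearson") {
    if (sd(s) == 0 || sd(t) == 0) {
      stop("constant map: Pearson expression undefined", call. = FALSE)
    }
    cor(s, t)
  } else {
    ns <- sqrt(sum(s^2)); nt <- sqrt(sum(t^2))
    if (ns == 0 || nt == 0) {
      stop("zero map: cosine expression undefined", call. = FALSE)
    }
    sum(s * t) / (ns * nt)
  }
}

#' Effective number of tests and corrected alpha
#'
#' Estimates the effective number of independent tests from a correlation
#' matrix, by either the eigenvalue-partition method
#' (`"liji"`: `m_eff = sum(1(lambda >= 1) + frac(lambda))` over eigenvalues
#' of the absolute correlation matrix) or the eigenvalue-variance method
#' (`"nyholt"`: `m_eff = 1 + (m - 1)(1 - var(lambda)/m)`), and divides the
#' family alpha by it.
#'
#' @param corr_matrix Symmetric correlation matrix with unit diagonal.
#' @param method `"liji"` or `"nyholt"`.
#' @param family_alpha Family-wise alpha (default 0.05).
#' @return Tibble with columns `m_eff`, `corrected_alpha`.
#' @export
effective_tests <- function(corr_matrix, method = c("liji", "nyholt"),
                            family_alpha = 0.05) {
  method <- match.arg(method)
  m <- nrow(corr_matrix)
  if (m != ncol(corr_matrix) || any(abs(diag(corr_matrix) - 1) > 1e-8)) {
    stop("need a square correlation matrix with unit diagonal", call. = FALSE)
  }
  if (max(abs(corr_matrix - t(corr_matrix))) > 1e-8) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  if (method == "liji") {
    lam <- eigen(abs(corr_matrix), symmetric = TRUE, only.values = TRUE)$values
    # round before the integer split so eigenvalues that are integers up to
    # numerical error (e.g. the all-ones matrix) do not gain a spurious
    # fractional part
    lam <- round(pmax(lam, 0), 10)
    m_eff <- sum(as.numeric(lam >= 1) + (lam - floor(lam)))
  } else {
    lam <- eigen(corr_matrix, symmetric = TRUE, only.values = TRUE)$values
    m_eff <- 1 + (m - 1) * (1 - var(lam) / m)
  }
  tibble::tibble(m_eff = m_eff, corrected_alpha = family_alpha / m_eff)
}
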