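# Spatial helpers shared by the template generator and cluster inference.

# 1D Gaussian kernel with given sigma in voxels (truncated at 3 sigma).
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma_vox))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolve the rows-dimension of a matrix with kernel k (zero padding).
conv_cols <- function(m, k) {
  d <- nrow(m)
  half <- (length(k) - 1L) / 2L
  B <- matrix(0, d, d)
  for (j in seq_along(k)) {
    off <- j - 1L - half
    idx <- seq_len(d)
    tgt <- idx + off
    ok <- tgt >= 1L & tgt <= d
    B[cbind(idx[ok], tgt[ok])] <- B[cbind(idx[ok], tgt[ok])] + k[j]
  }
  B %*% m
}

# Separable 3D Gaussian smoothing; `fwhm_mm` converted per-axis using voxel
# sizes. If a mask is given, smoothing is renormalised inside the mask so
# edge voxels are unbiased.
gaussian_smooth_3d <- function(arr, fwhm_mm, voxel_size = c(2, 2, 2), mask = NULL) {
  d <- dim(arr)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  sm <- function(a) {
    for (ax in 1:3) {
      k <- gaussian_kernel_1d(sig[ax])
      if (length(k) > 1L) {
        perm <- c(ax, setdiff(1:3, ax))
        ap <- aperm(a, perm)
        dp <- dim(ap)
        m <- conv_cols(matrix(ap, dp[1], dp[2] * dp[3]), k)
        a <- aperm(array(m, dp), order(perm))
      }
    }
    a
  }
  if (is.null(mask)) return(sm(arr))
  m0 <- array(0, d)
  m0[mask] <- arr[mask]
  num <- sm(m0)
  den <- sm(array(as.numeric(mask), d))
  out <- array(0, d)
  out[mask] <- num[mask] / den[mask]
  out
}

# Label connected components of a 3D logical array (26-connectivity).
# Returns an integer array (0 = background) and attribute "sizes".
label_clusters_26 <- function(bin) {
  d <- dim(bin)
  lab <- array(0L, d)
  idx <- which(bin)
  if (length(idx) == 0L) {
    attr(lab, "sizes") <- integer(0)
    return(lab)
  }
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
  lin_off <- off[, 1] + off[, 2] * d[1] + off[, 3] * d[1] * d[2]
  coord <- arrayInd(idx, d)
  in_set <- array(FALSE, d); in_set[idx] <- TRUE
  nlab <- 0L
  sizes <- integer(0)
  for (s in idx) {
    if (lab[s] != 0L) next
    nlab <- nlab + 1L
    queue <- s
    lab[s] <- nlab
    count <- 0L
    while (length(queue) > 0L) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      count <- count + 1L
      ci <- arrayInd(v, d)
      for (j in seq_len(nrow(off))) {
        n1 <- ci[1] + off[j, 1]; n2 <- ci[2] + off[j, 2]; n3 <- ci[3] + off[j, 3]
        if (n1 < 1L || n1 > d[1] || n2 < 1L || n2 > d[2] || n3 < 1L || n3 > d[3]) next
        nv <- n1 + (n2 - 1L) * d[1] + (n3 - 1L) * d[1] * d[2]
        if (in_set[nv] && lab[nv] == 0L) {
          lab[nv] <- nlab
          queue <- c(queue, nv)
        }
      }
    }
    sizes[nlab] <- count
  }
  attr(lab, "sizes") <- sizes
  lab
}

# Evaluate code with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
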