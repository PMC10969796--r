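# Shared voxel-grid helpers.  All separable filtering is done by banded
# kernel-matrix multiplication along one axis at a time, with the truncated
# kernel renormalized at the array edges so smoothing preserves local mean.

#' @keywords internal
shift3d <- function(a, dz = 0L, dy = 0L, dx = 0L, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- list(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  sft <- c(dz, dy, dx)
  dst <- src
  for (ax in 1:3) {
    s <- sft[ax]
    if (s == 0) next
    n <- d[ax]
    if (abs(s) >= n) return(out)
    if (s > 0) { dst[[ax]] <- (s + 1):n; src[[ax]] <- 1:(n - s) }
    else       { dst[[ax]] <- 1:(n + s); src[[ax]] <- (1 - s):n }
  }
  out[dst$z, dst$y, dst$x] <- a[src$z, src$y, src$x]
  out
}

#' @keywords internal
gaussKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' @keywords internal
boxKernel1d <- function(radius) {
  rep(1, 2 * radius + 1) / (2 * radius + 1)
}

# Band matrix for convolving a length-n axis with kernel k, rows
# renormalized where the kernel is truncated by the edge.
#' @keywords internal
convBandMatrix <- function(n, k) {
  half <- (length(k) - 1L) / 2L
  M <- matrix(0, n, n)
  for (off in seq(-half, half)) {
    idx <- seq_len(n)
    j <- idx + off
    ok <- j >= 1 & j <= n
    M[cbind(idx[ok], j[ok])] <- k[off + half + 1]
  }
  M / rowSums(M)
}

# Apply a 1D kernel along one axis (1 = z, 2 = y, 3 = x) of a 3D array.
#' @keywords internal
convAxis3d <- function(a, k, axis) {
  if (length(k) == 1L) return(a)
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  M <- convBandMatrix(dp[1], k)
  res <- M %*% matrix(ap, nrow = dp[1])
  res <- array(res, dp)
  aperm(res, order(perm))
}

#' @keywords internal
gaussFilter3d <- function(a, sigma) {
  # sigma: length-3 (z, y, x) in voxels
  for (ax in 1:3) a <- convAxis3d(a, gaussKernel1d(sigma[ax]), ax)
  a
}

#' @keywords internal
meanFilter3d <- function(a, radius = 1L) {
  if (radius < 1) return(a)
  k <- boxKernel1d(radius)
  for (ax in 1:3) a <- convAxis3d(a, k, ax)
  a
}

# min-max normalization; constant arrays map to all zeros
#' @keywords internal
normalize01 <- function(a) {
  rng <- range(a)
  if (rng[2] <= rng[1]) return(array(0, dim(a)))
  (a - rng[1]) / (rng[2] - rng[1])
}

# Otsu threshold of a numeric vector, delegated to EBImage on the
# min-max-normalized values; returns the cut on the original scale.
#' @keywords internal
otsuCut <- function(v, levels = 256L) {
  rng <- range(v)
  if (rng[2] <= rng[1]) stop("cannot threshold a constant signal")
  v01 <- (v - rng[1]) / (rng[2] - rng[1])
  img <- EBImage::Image(v01, dim = c(length(v01), 1L))
  thr <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  rng[1] + thr * (rng[2] - rng[1])
}

# ---- binary 3D morphology on the 6-neighbourhood (cross element) ----

#' @keywords internal
dilate3d <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) {
    mask <- mask |
      shift3d(mask,  1L, 0L, 0L, FALSE) | shift3d(mask, -1L, 0L, 0L, FALSE) |
      shift3d(mask, 0L,  1L, 0L, FALSE) | shift3d(mask, 0L, -1L, 0L, FALSE) |
      shift3d(mask, 0L, 0L,  1L, FALSE) | shift3d(mask, 0L, 0L, -1L, FALSE)
  }
  mask
}

#' @keywords internal
erode3d <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) {
    mask <- mask &
      shift3d(mask,  1L, 0L, 0L, FALSE) & shift3d(mask, -1L, 0L, 0L, FALSE) &
      shift3d(mask, 0L,  1L, 0L, FALSE) & shift3d(mask, 0L, -1L, 0L, FALSE) &
      shift3d(mask, 0L, 0L,  1L, FALSE) & shift3d(mask, 0L, 0L, -1L, FALSE)
  }
  mask
}

# Fill enclosed 3D cavities: background components not reaching any face of
# the array are holes.
#' @keywords internal
fillHoles3d <- function(mask) {
  bg <- !mask
  lab <- cc_label3d_cpp(as.vector(bg), dim(mask), 6L)
  dim(lab) <- dim(mask)
  d <- dim(mask)
  faceLabs <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                       lab[, , 1], lab[, , d[3]]))
  faceLabs <- faceLabs[faceLabs > 0]
  holes <- bg & !(lab %in% faceLabs)
  mask | holes
}

# Mask voxels 6-adjacent to background (or the array edge).
#' @keywords internal
maskBorder3d <- function(mask) {
  interior <- mask &
    shift3d(mask,  1L, 0L, 0L, FALSE) & shift3d(mask, -1L, 0L, 0L, FALSE) &
    shift3d(mask, 0L,  1L, 0L, FALSE) & shift3d(mask, 0L, -1L, 0L, FALSE) &
    shift3d(mask, 0L, 0L,  1L, FALSE) & shift3d(mask, 0L, 0L, -1L, FALSE)
  mask & !interior
}

# Robust noise-sd estimate from first differences along the fastest axis.
#' @keywords internal
robustNoiseSd <- function(a, mask = NULL) {
  d <- if (is.null(mask)) diff(as.vector(a)) else diff(a[mask])
  stats::mad(d) / sqrt(2)
}

# voxel-centre coordinates in micrometres for 1-based (z,y,x) indices;
# the centre of voxel (1,1,1) sits at voxelSize/2.
#' @keywords internal
voxelCentersUm <- function(idx, voxelSize) {
  sweep(sweep(idx - 0.5, 2, voxelSize, `*`), 2, 0, `+`)
}

#' @keywords internal
linearToZyx <- function(i, d) {
  i0 <- i - 1L
  z <- i0 %% d[1]
  r <- i0 %/% d[1]
  y <- r %% d[2]
  x <- r %/% d[2]
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}

#' @keywords internal
zyxToLinear <- function(zyx, d) {
  (zyx[, 1] - 1L) + d[1] * ((zyx[, 2] - 1L) + d[2] * (zyx[, 3] - 1L)) + 1L
}

#' @keywords internal
localSeed <- function(seed, code = 0L) {
  # derive independent sub-seeds below 2^31 from one user seed
  as.integer((as.numeric(seed) * 48271 + code * 1299709) %% 2147483629)
}
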