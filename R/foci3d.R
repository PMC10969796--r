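#' 3D replication-foci / spot segmentation
#'
#' Spots (replication foci, replicons, FISH signals) are segmented by a
#' combined seed-and-threshold approach: local intensity maxima on the
#' mean-filtered, normalized volume seed a region growing whose stopping
#' intensity comes from a Gaussian fit to the radial profile around each
#' seed; closely clustered spots are separated by a marker-based 3D
#' watershed.
#'
#' @name foci3d-module
NULL

# shared pre-processing for seed detection and region growing
processSpotVolume <- function(volume, meanRadius = 1L) {
  a <- imgData(volume)
  normalize01(meanFilter3d(a, meanRadius))
}

#' Detect spot seeds as 3D regional maxima
#'
#' The volume is mean-filtered (default pixel radius 1) and min-max
#' normalized; seeds are 26-neighbourhood regional maxima with prominence
#' at least \code{h}.  Candidates below the detection floor are ignored so
#' that regional maxima of pure background noise do not seed spots.
#'
#' @param volume a \code{VolumeImage} (typically already masked)
#' @param mask optional \code{NucleusMask} restricting the search
#' @param meanRadius mean-filter radius in pixels
#' @param h prominence ("noise tolerance") on the normalized scale, or
#'   \code{"auto"} for 3x the robust noise sd of the processed volume
#' @param floor detection floor on the normalized scale, or \code{"auto"}
#'   for the in-mask median plus 6x the robust noise sd
#' @return data.frame of seeds (z, y, x voxel indices, linear index,
#'   processed value), ordered by decreasing value, with the processed
#'   volume attached as attribute \code{"processed"}
#' @export
detectSeeds <- function(volume, mask = NULL, meanRadius = 1L, h = "auto",
                        floor = "auto") {
  a <- imgData(volume)
  mf <- meanFilter3d(a, meanRadius)
  rng <- range(mf)
  d <- dim(a)
  m <- if (is.null(mask)) array(TRUE, d) else maskArray(mask)
  if (!identical(dim(m), d)) stop("mask and volume shapes differ")
  empty <- data.frame(z = integer(0), y = integer(0), x = integer(0),
                      index = integer(0), value = numeric(0))
  if (rng[2] <= rng[1]) {
    attr(empty, "processed") <- array(0, d)
    attr(empty, "h") <- NA_real_
    attr(empty, "floor") <- NA_real_
    return(empty)
  }
  proc <- (mf - rng[1]) / (rng[2] - rng[1])
  # noise on the processed scale: raw read noise, attenuated by the mean
  # filter (uncorrelated-noise gain 1/sqrt(taps)), then normalized
  nTaps <- (2 * meanRadius + 1)^3
  noiseSd <- robustNoiseSd(a, m) / sqrt(nTaps) / (rng[2] - rng[1])
  hVal <- if (identical(h, "auto")) max(3 * noiseSd, 1e-6) else as.numeric(h)
  floorVal <- if (identical(floor, "auto"))
    median(proc[m]) + 6 * noiseSd else as.numeric(floor)
  idx <- find_maxima3d_cpp(as.vector(proc), as.vector(m), d, hVal, floorVal)
  if (length(idx) == 0) {
    attr(empty, "processed") <- proc
    attr(empty, "h") <- hVal
    attr(empty, "floor") <- floorVal
    return(empty)
  }
  zyx <- linearToZyx(idx, d)
  out <- data.frame(z = zyx[, 1], y = zyx[, 2], x = zyx[, 3],
                    index = as.integer(idx), value = proc[idx])
  attr(out, "processed") <- proc
  attr(out, "h") <- hVal
  attr(out, "floor") <- floorVal
  out
}

# radial mean intensity profile around a seed, distances in micrometres
radialProfile <- function(a, seed, voxelSize, rMax, binWidth) {
  d <- dim(a)
  ext <- ceiling(rMax / voxelSize)
  lo <- pmax(c(1L, 1L, 1L), seed - ext)
  hi <- pmin(d, seed + ext)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  dz2 <- ((zi - seed[1]) * voxelSize[1])^2
  dy2 <- ((yi - seed[2]) * voxelSize[2])^2
  dx2 <- ((xi - seed[3]) * voxelSize[3])^2
  r <- sqrt(outer(outer(dz2, dy2, `+`), dx2, `+`))
  v <- a[zi, yi, xi]
  keep <- r <= rMax
  bin <- floor(r[keep] / binWidth)
  prof <- tapply(v[keep], bin, mean)
  data.frame(r = (as.numeric(names(prof)) + 0.5) * binWidth,
             intensity = as.numeric(prof))
}

#' Gaussian-fit stopping threshold for seeded spot growth
#'
#' Fits \code{I(r) = A exp(-r^2 / (2 sigma^2)) + B} to the radial mean
#' profile around a seed (r in micrometres) and returns the threshold
#' \code{A exp(-k^2 / 2) + B}, i.e. the intensity k sigma from the centre.
#' A non-convergent fit or non-positive sigma falls back to the half-height
#' \code{B + (A - B) / 2} with \code{fallback = TRUE}.
#'
#' @param volume a \code{VolumeImage}, or a plain 3D array
#' @param seed voxel index (z, y, x) of a local maximum
#' @param k threshold location in sigmas from the spot centre
#' @param sigmaGuess initial sigma in micrometres (default 2 lateral
#'   voxels); the profile extends to 10x this radius in 0.5-voxel bins
#' @param voxelSize required when \code{volume} is a plain array
#' @return list with \code{threshold}, \code{A}, \code{B}, \code{sigma},
#'   \code{fallback}
#' @export
gaussianFitThreshold <- function(volume, seed, k = 2, sigmaGuess = NULL,
                                 voxelSize = NULL) {
  if (is(volume, "VolumeImage")) {
    a <- imgData(volume)
    vs <- replikit::voxelSize(volume)
  } else {
    a <- volume
    if (is.null(voxelSize)) stop("voxelSize required for a plain array")
    vs <- voxelSize
  }
  seed <- as.integer(seed)
  if (is.null(sigmaGuess)) sigmaGuess <- 2 * vs[2]
  binWidth <- 0.5 * min(vs)
  prof <- radialProfile(a, seed, vs, rMax = 10 * sigmaGuess,
                        binWidth = binWidth)
  A0 <- max(prof$intensity) - min(prof$intensity)
  B0 <- min(prof$intensity)
  fallback <- function() {
    list(threshold = B0 + A0 / 2, A = A0, B = B0, sigma = NA_real_,
         fallback = TRUE)
  }
  if (A0 <= 0 || nrow(prof) < 4) return(fallback())
  fit <- tryCatch(
    minpack.lm::nlsLM(intensity ~ A * exp(-r^2 / (2 * sigma^2)) + B,
                      data = prof,
                      start = list(A = A0, B = B0, sigma = sigmaGuess),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback())
  p <- stats::coef(fit)
  if (!is.finite(p["sigma"]) || p["sigma"] <= 0 || p["A"] <= 0)
    return(fallback())
  list(threshold = unname(p["A"] * exp(-k^2 / 2) + p["B"]),
       A = unname(p["A"]), B = unname(p["B"]),
       sigma = unname(abs(p["sigma"])), fallback = FALSE)
}

#' Segment 3D spots from seeds
#'
#' Each seed grows over 26-connected voxels at or above its own
#' Gaussian-fit threshold; overlapping claims are resolved by a
#' marker-based 3D watershed on the processed intensity (seeds as
#' markers).  Without the watershed, touching regions merge into one
#' object.  Objects smaller than \code{minVoxels} are removed and labels
#' renumbered 1..n.
#'
#' @param volume a \code{VolumeImage} (typically masked to the nucleus)
#' @param seeds seed table from \code{\link{detectSeeds}}, or NULL to
#'   detect internally
#' @param mask optional \code{NucleusMask}
#' @param k Gaussian-fit threshold parameter (sigmas from spot centre)
#' @param watershed split clustered spots with a marker-based watershed
#' @param minVoxels minimum object size in voxels
#' @param meanRadius mean-filter radius used for the processed volume
#' @return a \code{SpotLabelMap}; intensity statistics (sum, centroid) are
#'   computed from the original volume
#' @export
segmentSpots <- function(volume, seeds = NULL, mask = NULL, k = 2,
                         watershed = TRUE, minVoxels = 5L,
                         meanRadius = 1L) {
  vs <- voxelSize(volume)
  d <- dim(imgData(volume))
  if (is.null(seeds))
    seeds <- detectSeeds(volume, mask = mask, meanRadius = meanRadius)
  proc <- attr(seeds, "processed")
  if (is.null(proc)) proc <- processSpotVolume(volume, meanRadius)
  m <- if (is.null(mask)) array(TRUE, d) else maskArray(mask)

  emptyMap <- function() {
    new("SpotLabelMap", labels = array(0L, d), voxelSize = vs,
        table = data.frame(label = integer(0), n_voxels = integer(0),
                           volume_um3 = numeric(0), z_um = numeric(0),
                           y_um = numeric(0), x_um = numeric(0),
                           sum_intensity = numeric(0), seed = integer(0),
                           threshold = numeric(0), fallback = logical(0)))
  }
  if (nrow(seeds) == 0) return(emptyMap())

  fits <- lapply(seq_len(nrow(seeds)), function(i)
    gaussianFitThreshold(proc, c(seeds$z[i], seeds$y[i], seeds$x[i]), k = k,
                         voxelSize = vs))
  thr <- vapply(fits, `[[`, 0, "threshold")
  fallbackFlag <- vapply(fits, `[[`, TRUE, "fallback")

  ok <- proc[seeds$index] >= thr
  if (any(!ok))
    message(sprintf("dropped %d seed(s) below their own threshold",
                    sum(!ok)))
  if (!any(ok)) return(emptyMap())
  seeds <- seeds[ok, , drop = FALSE]
  thr <- thr[ok]
  fallbackFlag <- fallbackFlag[ok]

  grown <- grow_seeds3d_cpp(as.vector(proc), as.vector(m), d,
                            seeds$index, thr)
  dim(grown) <- d
  lab <- if (watershed) {
    marker_watershed3d_cpp(as.vector(proc), as.vector(grown), d,
                           seeds$index)
  } else {
    cc_label3d_cpp(as.vector(grown), d, 26L)
  }
  dim(lab) <- d

  nl <- max(lab)
  if (nl == 0) return(emptyMap())
  sizes <- tabulate(lab[lab > 0], nbins = nl)
  keep <- which(sizes >= minVoxels)
  if (length(keep) == 0) return(emptyMap())
  relab <- integer(nl)
  relab[keep] <- seq_along(keep)
  pos <- lab > 0
  lab[pos] <- relab[lab[pos]]

  a <- imgData(volume)
  idx <- which(lab > 0)
  lv <- lab[idx]
  f <- factor(lv, levels = seq_along(keep))
  w <- a[idx]
  # guard against non-positive weights in the centroid
  wPos <- pmax(w, 1e-12)
  zyx <- linearToZyx(idx, d)
  um <- voxelCentersUm(zyx, vs)
  wsum <- tapply(wPos, f, sum)
  cz <- tapply(wPos * um[, 1], f, sum) / wsum
  cy <- tapply(wPos * um[, 2], f, sum) / wsum
  cx <- tapply(wPos * um[, 3], f, sum) / wsum
  nvox <- as.integer(table(f))

  # seed bookkeeping: watershed label i corresponds to kept seed i
  seedIdx <- if (watershed) seeds$index[keep] else rep(NA_integer_,
                                                       length(keep))
  thrOut <- if (watershed) thr[keep] else rep(NA_real_, length(keep))
  fbOut <- if (watershed) fallbackFlag[keep] else rep(NA, length(keep))

  tab <- data.frame(label = seq_along(keep),
                    n_voxels = nvox,
                    volume_um3 = nvox * prod(vs),
                    z_um = as.numeric(cz), y_um = as.numeric(cy),
                    x_um = as.numeric(cx),
                    sum_intensity = as.numeric(tapply(w, f, sum)),
                    seed = seedIdx,
                    threshold = thrOut,
                    fallback = fbOut)
  new("SpotLabelMap", labels = lab, voxelSize = vs, table = tab)
}

#' Per-cell spot features: volumes, pairwise distances, border distances
#'
#' All-pairs centroid distances and centroid-to-border distances are
#' computed in micrometres, honouring the anisotropic voxel size.  The
#' border distance of a spot is the distance from its centroid to the
#' centre of the nearest mask voxel that touches background.
#'
#' @param labels a \code{SpotLabelMap}
#' @param mask a \code{NucleusMask}
#' @return list with \code{perSpot} (volume, centroid, border distance),
#'   \code{pairDistances} (data.frame i, j, distance_um), and \code{n}
#' @export
spotFeatures <- function(labels, mask) {
  tab <- spotTable(labels)
  vs <- voxelSize(labels)
  n <- nrow(tab)
  if (n == 0)
    return(list(perSpot = data.frame(label = integer(0),
                                     volume_um3 = numeric(0),
                                     border_dist_um = numeric(0)),
                pairDistances = data.frame(i = integer(0), j = integer(0),
                                           distance_um = numeric(0)),
                n = 0L))
  ctr <- as.matrix(tab[, c("z_um", "y_um", "x_um")])
  border <- maskBorder3d(maskArray(mask))
  bidx <- which(border, arr.ind = TRUE)
  bum <- voxelCentersUm(bidx, vs)
  borderDist <- vapply(seq_len(n), function(i) {
    sqrt(min(rowSums(sweep(bum, 2, ctr[i, ])^2)))
  }, 0)
  pairs <- if (n >= 2) {
    cmb <- utils::combn(n, 2)
    dd <- sqrt(rowSums((ctr[cmb[1, ], , drop = FALSE] -
                        ctr[cmb[2, ], , drop = FALSE])^2))
    data.frame(i = cmb[1, ], j = cmb[2, ], distance_um = dd)
  } else {
    data.frame(i = integer(0), j = integer(0), distance_um = numeric(0))
  }
  list(perSpot = data.frame(label = tab$label,
                            volume_um3 = tab$volume_um3,
                            border_dist_um = borderDist),
       pairDistances = pairs, n = n)
}
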