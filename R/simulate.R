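#' Specification for a simulated 3D nucleus
#'
#' Describes one synthetic multichannel nucleus: an ellipsoidal nuclear mask
#' on an anisotropic voxel grid, a DAPI channel whose intensity follows a
#' Potts-coupled compaction-class field, and any number of spot channels
#' (replication foci, FISH probes, replisome marks) with isotropic-in-um
#' Gaussian spots planted at recorded positions.
#'
#' Spots are defined in micrometre coordinates and then sampled onto the
#' anisotropic grid, so inter-spot distances are exact in physical units.
#' For a channel pair named in \code{colocPair}, the stated fraction of
#' spots in the first channel shares centroids with spots of the second.
#' If both an \code{EdU} and a \code{PCNA} channel are requested, the clean
#' EdU channel is \code{eduPcnaRatio} times the clean PCNA channel, so the
#' planted ratiometric fork-speed signal is exact before noise.
#'
#' @param shape image shape in voxels, order (z, y, x)
#' @param voxelSize voxel size in micrometres (z, y, x)
#' @param semiAxes nucleus ellipsoid semi-axes in micrometres (z, y, x)
#' @param nSpots named integer vector: spots per channel (e.g.
#'   \code{c(PCNA = 50, FISH = 20)}); may be empty for a DAPI-only nucleus
#' @param spotSigma Gaussian spot sigma in micrometres (isotropic)
#' @param spotAmplitude peak amplitude above background
#' @param background constant background level (a.u.)
#' @param noiseSd Gaussian read-noise standard deviation (0 = none)
#' @param poissonNoise add Poisson shot noise on the clean signal
#' @param placement spot placement mode: \code{"dispersed"} (uniform, early
#'   S-like), \code{"peripheral"} (shell, mid S-like) or \code{"clustered"}
#'   (aggregates, late S-like)
#' @param minSeparation minimum centroid separation in micrometres
#'   (default \code{4 * spotSigma})
#' @param colocPair character(2): channels (A, B) for which a fraction of
#'   A-spots is planted at B-spot centroids
#' @param colocFraction fraction in [0, 1] of colocalizing A-spots
#' @param eduPcnaRatio total EdU / total PCNA clean-signal ratio (> 0)
#' @param nClasses number of compaction classes in the DAPI field
#' @param beta Potts spatial coupling strength (>= 0) of the class field
#' @param classMeans DAPI mean intensity per class, strictly increasing;
#'   default is equally spaced from 40 to 220
#' @param gibbsSweeps fixed number of Gibbs sweeps for the Potts field
#' @param seed RNG seed; fixes all outputs exactly
#' @return a validated list of class \code{"nucleusSimSpec"}
#' @export
nucleusSimSpec <- function(shape = c(z = 24L, y = 96L, x = 96L),
                           voxelSize = DEFAULT_VOXEL_SIZE,
                           semiAxes = c(z = 2.6, y = 5, x = 5),
                           nSpots = c(PCNA = 50L),
                           spotSigma = 0.3,
                           spotAmplitude = 100,
                           background = 10,
                           noiseSd = 10,
                           poissonNoise = TRUE,
                           placement = c("dispersed", "peripheral",
                                         "clustered"),
                           minSeparation = NULL,
                           colocPair = NULL,
                           colocFraction = 0,
                           eduPcnaRatio = 1,
                           nClasses = 7L,
                           beta = 0.6,
                           classMeans = NULL,
                           gibbsSweeps = 50L,
                           seed = 1L) {
  placement <- match.arg(placement)
  if (length(shape) != 3L || any(shape < 1))
    stop("shape must be 3 positive voxel counts (z, y, x)")
  if (any(voxelSize <= 0)) stop("voxel sizes must be positive")
  if (spotSigma <= 0) stop("spotSigma must be positive")
  if (colocFraction < 0 || colocFraction > 1)
    stop("colocFraction must lie in [0, 1]")
  if (!is.null(colocPair) && length(colocPair) != 2L)
    stop("colocPair must name exactly two channels")
  if (eduPcnaRatio <= 0) stop("eduPcnaRatio must be > 0")
  if (nClasses < 1L) stop("nClasses must be >= 1")
  if (beta < 0) stop("beta must be >= 0")
  if (is.null(minSeparation)) minSeparation <- 4 * spotSigma
  if (is.null(classMeans))
    classMeans <- if (nClasses == 1L) background + 90
                  else seq(40, 220, length.out = nClasses)
  if (nClasses > 1L && is.unsorted(classMeans, strictly = TRUE))
    stop("classMeans must be strictly increasing")
  if (length(nSpots) && is.null(names(nSpots)))
    stop("nSpots must be a named vector (channel names)")
  spec <- list(shape = as.integer(shape), voxelSize = as.numeric(voxelSize),
               semiAxes = as.numeric(semiAxes), nSpots = nSpots,
               spotSigma = spotSigma, spotAmplitude = spotAmplitude,
               background = background, noiseSd = noiseSd,
               poissonNoise = poissonNoise, placement = placement,
               minSeparation = minSeparation, colocPair = colocPair,
               colocFraction = colocFraction, eduPcnaRatio = eduPcnaRatio,
               nClasses = as.integer(nClasses), beta = beta,
               classMeans = classMeans, gibbsSweeps = as.integer(gibbsSweeps),
               seed = as.integer(seed))
  class(spec) <- "nucleusSimSpec"
  spec
}

# ellipsoid membership of voxel centres, in micrometres
ellipsoidMask <- function(shape, voxelSize, semiAxes) {
  ctr <- shape * voxelSize / 2
  z <- (seq_len(shape[1]) - 0.5) * voxelSize[1]
  y <- (seq_len(shape[2]) - 0.5) * voxelSize[2]
  x <- (seq_len(shape[3]) - 0.5) * voxelSize[3]
  Z2 <- ((z - ctr[1]) / semiAxes[1])^2
  Y2 <- ((y - ctr[2]) / semiAxes[2])^2
  X2 <- ((x - ctr[3]) / semiAxes[3])^2
  q <- outer(outer(Z2, Y2, `+`), X2, `+`)
  q <= 1
}

# rejection-sample spot centres (um) inside the ellipsoid shrunk by margin,
# honouring a minimum pairwise separation
placeSpots <- function(n, shape, voxelSize, semiAxes, margin, minSep,
                       placement, avoid = NULL) {
  if (n == 0) return(matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, c("z", "y", "x"))))
  ctr <- shape * voxelSize / 2
  ax <- pmax(semiAxes - margin, 0.1)
  pts <- matrix(NA_real_, n, 3)
  colnames(pts) <- c("z", "y", "x")
  nClusters <- max(1L, round(n / 8))
  clusterCtr <- NULL
  if (placement == "clustered") {
    u <- matrix(stats::runif(nClusters * 3, -1, 1), ncol = 3)
    keep <- rowSums(u^2) <= 1
    while (sum(keep) < nClusters) {
      u <- rbind(u[keep, , drop = FALSE],
                 matrix(stats::runif(nClusters * 3, -1, 1), ncol = 3))
      keep <- rowSums(u^2) <= 1
    }
    clusterCtr <- sweep(u[seq_len(nClusters), , drop = FALSE] * 0.6, 2, ax,
                        `*`)
  }
  placed <- 0L
  tries <- 0L
  maxTries <- 2000L * n
  while (placed < n && tries < maxTries) {
    tries <- tries + 1L
    if (placement == "dispersed") {
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) > 1) next
      p <- u * ax
    } else if (placement == "peripheral") {
      v <- stats::rnorm(3)
      v <- v / sqrt(sum(v^2))
      r <- stats::runif(1, 0.75, 0.95)
      p <- v * r * ax
    } else {
      ci <- sample.int(nClusters, 1L)
      p <- clusterCtr[ci, ] + stats::rnorm(3, sd = 1.5 * minSep)
      if (sum((p / ax)^2) > 1) next
    }
    cand <- p + ctr
    if (placed > 0L) {
      dmin <- min(sqrt(rowSums(sweep(pts[seq_len(placed), , drop = FALSE],
                                     2, cand)^2)))
      if (dmin < minSep) next
    }
    if (!is.null(avoid) && nrow(avoid) > 0) {
      dmin <- min(sqrt(rowSums(sweep(avoid, 2, cand)^2)))
      if (dmin < minSep) next
    }
    placed <- placed + 1L
    pts[placed, ] <- cand
  }
  if (placed < n)
    stop(sprintf("could not place %d of %d spots at separation %.2f um",
                 n - placed, n, minSep))
  pts
}

# render isotropic Gaussian spots (um) onto the anisotropic voxel grid
renderSpots <- function(shape, voxelSize, centers, sigma, amplitude) {
  vol <- array(0, shape)
  if (nrow(centers) == 0) return(vol)
  ext <- 4 * sigma
  amps <- rep_len(amplitude, nrow(centers))
  for (i in seq_len(nrow(centers))) {
    c_um <- centers[i, ]
    lo <- pmax(1L, floor((c_um - ext) / voxelSize - 0.5) + 1L)
    hi <- pmin(shape, ceiling((c_um + ext) / voxelSize + 0.5))
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    dz2 <- ((zi - 0.5) * voxelSize[1] - c_um[1])^2
    dy2 <- ((yi - 0.5) * voxelSize[2] - c_um[2])^2
    dx2 <- ((xi - 0.5) * voxelSize[3] - c_um[3])^2
    g <- outer(outer(dz2, dy2, `+`), dx2, `+`)
    vol[zi, yi, xi] <- vol[zi, yi, xi] + amps[i] * exp(-g / (2 * sigma^2))
  }
  vol
}

#' Simulate one multichannel 3D nucleus with planted ground truth
#'
#' Generates an ellipsoidal nucleus, a DAPI channel driven by a
#' Potts-coupled compaction-class field (class means strictly increasing
#' with class label), and the requested spot channels.  All randomness is
#' governed by \code{spec$seed}; identical specs give bit-identical output.
#'
#' @param spec a \code{\link{nucleusSimSpec}}
#' @return list with \code{channels} (named list of \code{VolumeImage},
#'   including \code{DAPI}), \code{mask} (logical ground-truth nuclear
#'   mask), and \code{truth}: a list with the planted \code{spots} table
#'   (channel, spot, centroid in um and voxels, sigma, amplitude),
#'   \code{classField} (integer array, 0 outside), \code{colocCount},
#'   and \code{eduPcnaRatio}.
#' @export
simulateNucleus <- function(spec) {
  stopifnot(inherits(spec, "nucleusSimSpec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  shape <- spec$shape
  vs <- spec$voxelSize
  mask <- ellipsoidMask(shape, vs, spec$semiAxes)

  # compaction class field
  if (spec$nClasses > 1L) {
    lab <- array(0L, shape)
    lab[mask] <- sample.int(spec$nClasses, sum(mask), replace = TRUE)
    if (spec$beta > 0)
      lab <- array(gibbs_potts3d_cpp(as.vector(lab), shape, spec$nClasses,
                                     spec$beta, spec$gibbsSweeps), shape)
  } else {
    lab <- array(0L, shape)
    lab[mask] <- 1L
  }
  dapiClean <- array(spec$background, shape)
  dapiClean[mask] <- spec$classMeans[lab[mask]]

  # spot channels; for a colocalization pair the reference channel (B) is
  # placed first so that non-colocalizing A spots can be kept at least
  # minSeparation away from every B spot
  chNames <- names(spec$nSpots)
  pair <- spec$colocPair
  if (!is.null(pair)) {
    if (!all(pair %in% chNames))
      stop("colocPair channels must be listed in nSpots")
    chNames <- c(setdiff(chNames, pair[1]), pair[1])
  }
  centers <- list()
  margin <- 2 * spec$spotSigma
  for (ch in chNames) {
    avoid <- if (!is.null(pair) && ch == pair[1]) centers[[pair[2]]]
             else NULL
    centers[[ch]] <- placeSpots(spec$nSpots[[ch]], shape, vs, spec$semiAxes,
                                margin, spec$minSeparation, spec$placement,
                                avoid = avoid)
  }
  chNames <- names(spec$nSpots)

  colocCount <- 0L
  if (!is.null(pair) && spec$colocFraction > 0) {
    a <- pair[1]; b <- pair[2]
    m <- round(spec$colocFraction * nrow(centers[[a]]))
    m <- min(m, nrow(centers[[b]]))
    if (m > 0) centers[[a]][seq_len(m), ] <- centers[[b]][seq_len(m), ]
    colocCount <- as.integer(m)
  }

  clean <- list()
  for (ch in chNames) {
    clean[[ch]] <- array(spec$background, shape) +
      renderSpots(shape, vs, centers[[ch]], spec$spotSigma,
                  spec$spotAmplitude)
  }
  # ratiometric EdU/PCNA coupling: clean EdU is an exact multiple of PCNA
  if (all(c("EdU", "PCNA") %in% chNames))
    clean[["EdU"]] <- spec$eduPcnaRatio * clean[["PCNA"]]

  addNoise <- function(x) {
    if (spec$poissonNoise) x <- array(stats::rpois(length(x), pmax(x, 0)),
                                      dim(x))
    if (spec$noiseSd > 0) x <- x + stats::rnorm(length(x), sd = spec$noiseSd)
    x
  }

  channels <- list(DAPI = VolumeImage(addNoise(dapiClean), vs))
  for (ch in chNames)
    channels[[ch]] <- VolumeImage(addNoise(clean[[ch]]), vs)

  spots <- do.call(rbind, lapply(chNames, function(ch) {
    ctr <- centers[[ch]]
    if (nrow(ctr) == 0)
      return(NULL)
    data.frame(channel = ch, spot = seq_len(nrow(ctr)),
               z_um = ctr[, 1], y_um = ctr[, 2], x_um = ctr[, 3],
               z_vox = ctr[, 1] / vs[1] + 0.5,
               y_vox = ctr[, 2] / vs[2] + 0.5,
               x_vox = ctr[, 3] / vs[3] + 0.5,
               sigma_um = spec$spotSigma,
               amplitude = spec$spotAmplitude)
  }))
  if (is.null(spots))
    spots <- data.frame(channel = character(0), spot = integer(0),
                        z_um = numeric(0), y_um = numeric(0),
                        x_um = numeric(0), z_vox = numeric(0),
                        y_vox = numeric(0), x_vox = numeric(0),
                        sigma_um = numeric(0), amplitude = numeric(0))

  list(channels = channels,
       mask = mask,
       truth = list(spots = spots, classField = lab,
                    colocCount = colocCount,
                    eduPcnaRatio = spec$eduPcnaRatio),
       spec = spec)
}

#' Simulate a 2D high-throughput cell population for cell-cycle gating
#'
#' Emulates per-nucleus DAPI and EdU sum intensities of an asynchronous
#' population: DAPI around 1x DNA content for G1, 2x for G2, in between for
#' S; EdU is elevated only in S cells.  Phase counts are assigned
#' deterministically from the requested fractions (largest-remainder
#' rounding), so the planted composition is exact.
#'
#' @param n number of cells
#' @param fractions named numeric (G1, S, G2), non-negative, summing to 1
#' @param dapiG1 mean DAPI sum of the G1 (1x DNA) population
#' @param dapiCv coefficient of variation of DAPI within a phase
#' @param eduNeg,eduPos mean EdU level of non-replicating / replicating cells
#' @param eduCv coefficient of variation of EdU
#' @param seed RNG seed
#' @return list with \code{cells} (data.frame: cell, dapi, edu) and
#'   \code{truth} (data.frame with the planted phase per cell plus counts)
#' @export
simulatePopulation <- function(n = 500L,
                               fractions = c(G1 = 0.4, S = 0.4, G2 = 0.2),
                               dapiG1 = 1000, dapiCv = 0.05,
                               eduNeg = 20, eduPos = 400, eduCv = 0.15,
                               seed = 1L) {
  if (any(fractions < 0)) stop("phase fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-6) stop("phase fractions must sum to 1")
  phases <- c("G1", "S", "G2")
  fr <- fractions[phases]
  fr[is.na(fr)] <- 0
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  base <- floor(fr * n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(fr * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  counts <- stats::setNames(as.integer(base), phases)
  phase <- sample(rep(phases, counts))

  dapiMean <- c(G1 = dapiG1, S = 1.5 * dapiG1, G2 = 2 * dapiG1)[phase]
  dapi <- stats::rnorm(n, dapiMean, dapiCv * dapiMean)
  isS <- phase == "S"
  # S cells span the 1x-2x range as replication proceeds
  dapi[isS] <- stats::runif(sum(isS), 1.05 * dapiG1, 1.95 * dapiG1)
  eduMean <- ifelse(isS, eduPos, eduNeg)
  edu <- pmax(0, stats::rnorm(n, eduMean, eduCv * eduMean))
  dapi <- pmax(dapi, 1)

  list(cells = data.frame(cell = seq_len(n), dapi = dapi, edu = edu),
       truth = list(phase = data.frame(cell = seq_len(n), phase = phase),
                    counts = counts))
}

#' Simulate a replication-origin interval set with known gap structure
#'
#' Plants origin peaks along each chromosome with known inter-origin gaps
#' (distances between successive peak midpoints), emulating an SNS-seq peak
#' file.
#'
#' @param nPerChrom named integer vector: peaks per chromosome
#' @param gaps either a numeric vector of gaps (bp, recycled per
#'   chromosome) or a function \code{function(n)} returning \code{n}
#'   positive gaps; the default draws log-normal gaps with the requested
#'   mean
#' @param meanGap mean gap in bp for the default log-normal sampler
#' @param peakWidth interval width in bp (>= 2)
#' @param firstMid midpoint of the first peak on every chromosome
#' @param seed RNG seed
#' @return list with \code{origins} (an \code{\link{OriginSet}}) and
#'   \code{truth} (per-chromosome mids and gaps)
#' @export
simulateOriginSet <- function(nPerChrom = c(chr1 = 100L),
                              gaps = NULL, meanGap = 34300,
                              peakWidth = 200L, firstMid = 10000L,
                              seed = 1L) {
  if (is.null(names(nPerChrom)))
    stop("nPerChrom must be named by chromosome")
  if (peakWidth < 2L) stop("peakWidth must be >= 2")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  sampler <- if (is.function(gaps)) {
    gaps
  } else if (is.numeric(gaps)) {
    function(n) rep_len(gaps, n)
  } else {
    # log-normal with sdlog 0.6, rescaled to the requested mean
    function(n) {
      g <- stats::rlnorm(n, meanlog = log(meanGap) - 0.18, sdlog = 0.6)
      pmax(round(g), peakWidth + 1)
    }
  }

  rows <- list()
  truth <- list()
  for (chrom in names(nPerChrom)) {
    np <- nPerChrom[[chrom]]
    g <- if (np > 1L) sampler(np - 1L) else numeric(0)
    if (any(g <= 0)) stop("gaps must be positive")
    if (any(g <= peakWidth))
      stop("gaps must exceed peakWidth to keep intervals non-overlapping")
    mids <- firstMid + c(0, cumsum(g))
    start0 <- as.integer(round(mids - peakWidth / 2))
    end0 <- start0 + as.integer(peakWidth)
    rows[[chrom]] <- data.frame(chrom = chrom, start = start0, end = end0)
    midsOut <- as.integer(floor((start0 + end0) / 2))
    truth[[chrom]] <- list(mids = midsOut, gaps = as.numeric(diff(midsOut)))
  }
  df <- do.call(rbind, rows)
  list(origins = originSet(df$chrom, df$start, df$end), truth = truth)
}
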