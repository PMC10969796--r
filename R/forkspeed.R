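#' Ratiometric fork-speed proxy
#'
#' The ratio of total incorporated-nucleotide signal (EdU) to total
#' replisome signal (PCNA) in a nucleus reports DNA synthesized per active
#' replisome: a ratio <= 1 indicates EdU confined within PCNA foci (slow
#' forks), > 1 indicates faster forks.  Raw ratios are normalized to the
#' population median per group (cell line), making them invariant to
#' channel gains.
#'
#' @name forkspeed-module
NULL

# histogram-mode estimate of a background level
backgroundMode <- function(v) {
  if (length(v) < 10) return(min(v))
  d <- stats::density(v, n = 512)
  d$x[which.max(d$y)]
}

# in-mask voxels outside foci: voxels robustly above background in ANY of
# the supplied channels are excluded together with a dilation ring, so
# spot flanks do not contaminate the background estimate.  A single
# exclusion region shared by both channels keeps residual flank
# contamination proportional between them, which cancels in the ratio.
outsideFociVoxels <- function(channels, m, dilateIter = 4L) {
  excl <- array(FALSE, dim(m))
  for (a in channels) {
    v <- a[m]
    s <- stats::mad(v)
    if (s > 0) excl <- excl | ((a > stats::median(v) + 3 * s) & m)
  }
  if (any(excl)) excl <- dilate3d(excl, dilateIter)
  keep <- m & !excl
  if (sum(keep) < max(1000, 0.05 * sum(m))) return(m)
  keep
}

#' EdU/PCNA fork-speed ratio for one nucleus
#'
#' Mode \code{"sum"} computes the ratio of background-subtracted intensity
#' sums inside the nuclear mask; mode \code{"volume"} computes the ratio
#' of total segmented spot volumes of the two channels.
#'
#' @param edu,pcna co-registered \code{VolumeImage}s
#' @param mask a \code{NucleusMask}
#' @param mode \code{"sum"} or \code{"volume"}
#' @param background \code{"mean"} (default: per-channel mean of the
#'   in-mask voxels outside foci, foci excluded jointly across channels),
#'   \code{"mode"} (histogram mode of the same voxels), \code{"none"}, or
#'   a numeric length-2 vector (EdU, PCNA)
#' @param ... passed to \code{\link{segmentSpots}} in volume mode
#' @return list with \code{ratio}, \code{eduTotal}, \code{pcnaTotal},
#'   \code{mode}
#' @export
forkRatio <- function(edu, pcna, mask, mode = c("sum", "volume"),
                      background = "mean", ...) {
  mode <- match.arg(mode)
  m <- maskArray(mask)
  if (!identical(dim(imgData(edu)), dim(imgData(pcna))) ||
      !identical(dim(imgData(edu)), dim(m)))
    stop("EdU, PCNA and mask shapes differ")
  if (mode == "sum") {
    ea <- imgData(edu)
    pa <- imgData(pcna)
    ev <- ea[m]
    pv <- pa[m]
    bg <- if (identical(background, "mean") ||
              identical(background, "mode")) {
      keep <- outsideFociVoxels(list(ea, pa), m)
      if (identical(background, "mean"))
        c(mean(ea[keep]), mean(pa[keep]))
      else
        c(backgroundMode(ea[keep]), backgroundMode(pa[keep]))
    } else if (identical(background, "none")) {
      c(0, 0)
    } else as.numeric(background)
    # no clipping: zero-mean noise residuals cancel in the sums, keeping
    # the estimator unbiased
    eTot <- sum(ev - bg[1])
    pTot <- sum(pv - bg[2])
  } else {
    eSpots <- segmentSpots(maskChannel(edu, mask), mask = mask, ...)
    pSpots <- segmentSpots(maskChannel(pcna, mask), mask = mask, ...)
    eTot <- sum(spotTable(eSpots)$volume_um3)
    pTot <- sum(spotTable(pSpots)$volume_um3)
  }
  if (pTot <= 0)
    stop("no PCNA signal detected (active replisomes absent); ",
         "fork ratio undefined")
  list(ratio = eTot / pTot, eduTotal = eTot, pcnaTotal = pTot, mode = mode)
}

#' Normalize fork ratios to the group median
#'
#' Each raw ratio is divided by the median of its group (cell line, or
#' cell line x experiment), so the normalized group median is exactly 1
#' and global channel gains cancel.
#'
#' @param ratios numeric raw ratios
#' @param groups grouping vector (default: one group)
#' @return numeric normalized ratios
#' @export
normalizeRatios <- function(ratios, groups = NULL) {
  if (length(ratios) == 0) stop("empty ratio vector")
  if (is.null(groups)) groups <- rep(1L, length(ratios))
  if (length(groups) != length(ratios))
    stop("groups must match ratios in length")
  out <- numeric(length(ratios))
  for (g in unique(groups)) {
    sel <- groups == g
    md <- median(ratios[sel])
    if (!is.finite(md) || md <= 0)
      stop("non-positive group median; cannot normalize group ", g)
    out[sel] <- ratios[sel] / md
  }
  out
}
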