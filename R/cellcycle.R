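#' High-throughput cell-cycle profiling and duration arithmetic
#'
#' Per-nucleus DAPI sum intensity reports total DNA content (1x in G1, 2x
#' in G2, in between during S) and EdU intensity separates replicating from
#' non-replicating cells.  Together with the culture doubling time this
#' yields absolute phase and sub-stage durations.
#'
#' @name cellcycle-module
NULL

#' Sum-project a volume along z
#'
#' @param volume a \code{VolumeImage}
#' @return 2D numeric matrix (y, x); no clipping is applied
#' @export
projectSum <- function(volume) {
  a <- imgData(volume)
  if (dim(a)[1] == 0) stop("volume has no z-planes")
  colSums(a, dims = 1)
}

#' Segment nuclei in a 2D projection
#'
#' Classical DAPI nucleus detector: Gaussian smoothing, Otsu threshold,
#' distance-transform watershed to separate touching nuclei, and an object
#' area filter.
#'
#' @param image 2D numeric matrix
#' @param sigma Gaussian smoothing sigma in pixels
#' @param minArea,maxArea object area bounds in pixels
#' @param split separate touching nuclei by watershed
#' @return integer label matrix (0 = background)
#' @export
segmentNuclei2D <- function(image, sigma = 2, minArea = 50,
                            maxArea = Inf, split = TRUE) {
  if (length(dim(image)) != 2L) stop("image must be 2D")
  rng <- range(image)
  if (rng[2] <= rng[1]) return(matrix(0L, nrow(image), ncol(image)))
  img <- EBImage::Image((image - rng[1]) / (rng[2] - rng[1]))
  sm <- EBImage::gblur(img, sigma = sigma)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  bw <- sm > thr
  lab <- if (split) {
    dm <- EBImage::distmap(bw)
    EBImage::watershed(dm, tolerance = 1, ext = 1)
  } else {
    EBImage::bwlabel(bw)
  }
  lab <- EBImage::imageData(lab)
  areas <- tabulate(lab[lab > 0])
  drop <- which(areas < minArea | areas > maxArea)
  if (length(drop)) lab[lab %in% drop] <- 0L
  keep <- sort(unique(lab[lab > 0]))
  relab <- integer(max(lab, 1L))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0
  out[pos] <- relab[lab[pos]]
  out
}

#' Measure per-nucleus DAPI and EdU intensities from a 2D label map
#'
#' @param labels integer label matrix from \code{\link{segmentNuclei2D}}
#' @param dapi,edu 2D intensity matrices aligned with \code{labels}
#' @param eduStat summarize EdU per nucleus by \code{"sum"} or
#'   \code{"mean"} (the field convention varies; sum is the default)
#' @return data.frame with cell, area, dapi, edu
#' @export
measureNuclei2D <- function(labels, dapi, edu, eduStat = c("sum", "mean")) {
  eduStat <- match.arg(eduStat)
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0)
    return(data.frame(cell = integer(0), area = integer(0),
                      dapi = numeric(0), edu = numeric(0)))
  f <- factor(labels[labels > 0], levels = ids)
  dapiSum <- tapply(dapi[labels > 0], f, sum)
  eduVal <- if (eduStat == "sum") tapply(edu[labels > 0], f, sum)
            else tapply(edu[labels > 0], f, mean)
  data.frame(cell = as.integer(ids),
             area = as.integer(table(f)),
             dapi = as.numeric(dapiSum),
             edu = as.numeric(eduVal))
}

# locate the two dominant modes of a DAPI distribution; NULL when the
# distribution lacks two well-separated DNA-content peaks (the G2 mode of
# a genuine profile sits near twice the G1 mode)
dapiModes <- function(dapi) {
  d <- stats::density(dapi, n = 512)
  i <- which(diff(sign(diff(d$y))) == -2) + 1
  i <- i[d$y[i] >= 0.05 * max(d$y)]
  if (length(i) < 2) return(NULL)
  i <- i[order(d$y[i], decreasing = TRUE)][1:2]
  m <- sort(d$x[i])
  if (m[2] / m[1] < 1.3) return(NULL)
  m
}

#' Gate cells into cell-cycle phases from DAPI and EdU intensities
#'
#' Cells above the EdU threshold are S phase; the remainder are split into
#' G1 and G2 at a DAPI cutoff between the 1x and 2x DNA-content modes.
#' The automatic EdU threshold is Otsu on \code{log1p(edu)}; the automatic
#' DAPI cutoff is the midpoint of the two largest modes of the non-S DAPI
#' distribution.
#'
#' @param records data.frame with columns \code{dapi} and \code{edu}
#' @param eduThreshold \code{"auto"} or a numeric manual threshold
#' @param dapiCutoff \code{"auto"} or a numeric manual G1/G2 cutoff
#' @return list with \code{records} (input plus \code{phase}),
#'   \code{fractions} (named, sums to 1), \code{eduThreshold},
#'   \code{dapiCutoff}
#' @export
gateCellCycle <- function(records, eduThreshold = "auto",
                          dapiCutoff = "auto") {
  stopifnot(all(c("dapi", "edu") %in% names(records)))
  if (any(records$dapi < 0) || any(records$edu < 0))
    stop("intensities must be non-negative")
  auto <- identical(eduThreshold, "auto") || identical(dapiCutoff, "auto")
  if (auto && nrow(records) < 20)
    stop("automatic thresholding needs at least 20 cells; ",
         "supply manual eduThreshold and dapiCutoff")

  eduThr <- if (identical(eduThreshold, "auto")) {
    if (stats::sd(records$edu) == 0) max(records$edu)  # no EdU signal: no S
    else expm1(otsuCut(log1p(records$edu)))
  } else as.numeric(eduThreshold)
  isS <- records$edu > eduThr

  nonS <- records$dapi[!isS]
  dapiCut <- if (identical(dapiCutoff, "auto")) {
    if (length(nonS) < 2) stop("no non-S cells to place the G1/G2 cutoff")
    modes <- dapiModes(nonS)
    if (is.null(modes))
      stop("DAPI histogram of non-S cells looks unimodal; ",
           "supply a manual dapiCutoff")
    mean(modes)
  } else as.numeric(dapiCutoff)

  phase <- ifelse(isS, "S", ifelse(records$dapi <= dapiCut, "G1", "G2"))
  records$phase <- factor(phase, levels = c("G1", "S", "G2"))
  fr <- prop.table(table(records$phase))
  list(records = records,
       fractions = stats::setNames(as.numeric(fr), names(fr)),
       eduThreshold = eduThr, dapiCutoff = dapiCut)
}

#' Population doubling time from two cell counts
#'
#' \code{dt = log(2) * deltaT / (log(N2) - log(N1))}; the logarithm base
#' cancels in the ratio.
#'
#' @param n1,n2 cell counts at the two time points (\code{n2 > n1})
#' @param deltaT hours between the counts
#' @return doubling time in hours
#' @export
doublingTime <- function(n1, n2, deltaT) {
  if (n1 <= 0 || n2 <= 0) stop("cell counts must be positive")
  if (deltaT <= 0) stop("deltaT must be positive")
  if (n2 <= n1) stop("population is not growing (N2 <= N1); ",
                     "doubling time undefined")
  log(2) * deltaT / (log(n2) - log(n1))
}

#' Phase or sub-stage durations from population fractions
#'
#' Each duration is the fraction of cells in that phase (or S sub-stage)
#' multiplied by the doubling time.
#'
#' @param fractions named numeric fractions in [0, 1], summing to <= 1
#' @param dt doubling time in hours
#' @return named numeric durations in hours
#' @export
phaseDurations <- function(fractions, dt) {
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]")
  if (sum(fractions) > 1 + 1e-8)
    stop("fractions must sum to at most 1")
  if (dt <= 0) stop("doubling time must be positive")
  fractions * dt
}
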