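#' Repli-FISH replication-timing measurement
#'
#' Replication timing of repeat elements is read out by intersecting
#' binary masks of replication foci (RFi) and FISH probe signals with a
#' voxelwise AND: connected components of the intersection are the
#' colocalizing (i.e. currently replicating) repeats.  Probe intensity
#' within the RFi masks, normalized per probe and cell line to the early-S
#' (S I) median, yields a per-stage timing profile.
#'
#' @name replifish-module
NULL

# accept SpotLabelMap, NucleusMask, VolumeImage or plain array as a mask
asBinaryArray <- function(x) {
  if (is(x, "SpotLabelMap")) return(labelArray(x) > 0)
  if (is(x, "NucleusMask")) return(maskArray(x))
  if (is(x, "VolumeImage")) return(imgData(x) > 0)
  if (is.array(x)) return(x > 0)
  stop("cannot interpret object of class ", class(x)[1], " as a 3D mask")
}

#' AND-logic colocalization of two binary masks
#'
#' Voxelwise conjunction; 26-connected components of the intersection are
#' counted as colocalizing objects.
#'
#' @param maskA,maskB same-shape masks (\code{SpotLabelMap},
#'   \code{NucleusMask}, \code{VolumeImage} or logical array)
#' @param voxelSize voxel size in micrometres; taken from the inputs when
#'   available
#' @return list with \code{intersection} (integer label array),
#'   \code{nObjects}, \code{objectVolumes_um3}, and
#'   \code{fractionA}: the fraction of A-objects intersecting B (defined
#'   when A carries labels)
#' @export
andColocalize <- function(maskA, maskB, voxelSize = NULL) {
  a <- asBinaryArray(maskA)
  b <- asBinaryArray(maskB)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  if (is.null(voxelSize)) {
    voxelSize <- if (is(maskA, "SpotLabelMap") || is(maskA, "NucleusMask"))
      replikit::voxelSize(maskA)
    else if (is(maskB, "SpotLabelMap") || is(maskB, "NucleusMask"))
      replikit::voxelSize(maskB)
    else DEFAULT_VOXEL_SIZE
  }
  inter <- a & b
  lab <- cc_label3d_cpp(as.vector(inter), dim(a), 26L)
  dim(lab) <- dim(a)
  n <- max(lab)
  vols <- if (n > 0) tabulate(lab[lab > 0], nbins = n) * prod(voxelSize)
          else numeric(0)
  fracA <- NA_real_
  if (is(maskA, "SpotLabelMap") && nSpots(maskA) > 0) {
    la <- labelArray(maskA)
    hit <- unique(la[inter & la > 0])
    fracA <- length(hit) / nSpots(maskA)
  }
  list(intersection = lab, nObjects = n, objectVolumes_um3 = vols,
       fractionA = fracA)
}

#' Probe sum intensity within replication-foci masks
#'
#' @param probe a \code{VolumeImage} of the FISH probe channel
#' @param rfi RFi mask (\code{SpotLabelMap} or binary array)
#' @return total probe intensity over RFi voxels
#' @export
probeSignalInFoci <- function(probe, rfi) {
  m <- asBinaryArray(rfi)
  a <- imgData(probe)
  if (!identical(dim(a), dim(m))) stop("probe and RFi mask shapes differ")
  sum(a[m])
}

#' Replication-timing profile across S-phase stages
#'
#' Per cell, probe and cell line, the probe-in-RFi sum intensity is
#' normalized to the median of the S I (early S) cells of the same probe
#' and line, so a fold change of 1 marks the early-S reference level.
#'
#' @param measurements data.frame with columns \code{cell}, \code{probe},
#'   \code{stage} (values \code{"SI"}, \code{"SII"}, \code{"SIII"}),
#'   \code{value}, and optionally \code{line}
#' @param reference stage defining the normalization anchor
#' @param dropZero drop cells with zero probe-in-RFi signal instead of
#'   keeping them as fold change 0
#' @return the input with a \code{fold_change} column
#' @export
probeTimingProfile <- function(measurements, reference = "SI",
                               dropZero = FALSE) {
  req <- c("cell", "probe", "stage", "value")
  if (!all(req %in% names(measurements)))
    stop("measurements must have columns ", paste(req, collapse = ", "))
  df <- measurements
  if (!"line" %in% names(df)) df$line <- "all"
  if (dropZero) df <- df[df$value > 0, , drop = FALSE]
  key <- interaction(df$probe, df$line, drop = TRUE)
  fold <- rep(NA_real_, nrow(df))
  for (g in levels(key)) {
    sel <- key == g
    ref <- df$value[sel & df$stage == reference]
    if (length(ref) == 0)
      stop(sprintf("no %s cells for probe group '%s'; reference undefined",
                   reference, g))
    md <- median(ref)
    if (md <= 0)
      stop(sprintf("non-positive %s reference median for group '%s'",
                   reference, g))
    fold[sel] <- df$value[sel] / md
  }
  df$fold_change <- fold
  df
}

#' Count replicating repeats per cell
#'
#' Binarizes probe and RFi label maps, intersects them with AND, and
#' counts the 26-connected components: the number of repeat loci
#' replicating at fixation time.
#'
#' @param probeLabels,rfiLabels label maps (or masks) from the same cell
#' @return integer count
#' @export
replicatingRepeatCount <- function(probeLabels, rfiLabels) {
  andColocalize(probeLabels, rfiLabels)$nObjects
}

#' Triple association: replicating rDNA contacting RNA Pol I (RPA 194)
#'
#' Replicating rDNA is the AND of the rDNA and RFi masks; a replicating
#' rDNA component is "associated" when it shares at least one voxel with
#' the RPA 194 mask (optionally after dilating the RPA mask by
#' \code{tolerance} voxels to absorb registration slack).
#'
#' @param rdna,rfi,rpa co-registered label maps or masks
#' @param tolerance RPA mask dilation in voxels (6-neighbourhood)
#' @return list with \code{nReplicating}, \code{nAssociated},
#'   \code{fraction}
#' @export
tripleAssociation <- function(rdna, rfi, rpa, tolerance = 0L) {
  repl <- andColocalize(rdna, rfi)
  lab <- repl$intersection
  n <- repl$nObjects
  if (n == 0)
    return(list(nReplicating = 0L, nAssociated = 0L, fraction = NA_real_))
  rpaMask <- asBinaryArray(rpa)
  if (!identical(dim(rpaMask), dim(lab))) stop("mask shapes differ")
  if (tolerance > 0) rpaMask <- dilate3d(rpaMask, as.integer(tolerance))
  hit <- unique(lab[rpaMask & lab > 0])
  list(nReplicating = as.integer(n), nAssociated = length(hit),
       fraction = length(hit) / n)
}
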