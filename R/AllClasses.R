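#' @title Core data classes
#'
#' @description
#' The package represents one channel of a 3D acquisition as a
#' \code{VolumeImage}: a numeric 3D array with per-axis voxel size in
#' micrometres.  Arrays use \code{dim = c(nz, ny, nx)} so that
#' \code{arr[z, , ]} is one optical section, and the voxel size vector is
#' named \code{c(z, y, x)}.  The default geometry matches a 100x confocal
#' acquisition: 0.125 x 0.125 um laterally and 0.29 um axially.
#'
#' @name replikit-classes
NULL

#' Default confocal voxel size in micrometres (z, y, x)
#' @keywords internal
DEFAULT_VOXEL_SIZE <- c(z = 0.29, y = 0.125, x = 0.125)

setClass("VolumeImage",
  representation(data = "array", voxelSize = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("data must be a 3D array (z, y, x)")
    vs <- object@voxelSize
    if (length(vs) != 3L || any(!is.finite(vs)) || any(vs <= 0))
      return("voxelSize must be 3 positive values (z, y, x) in micrometres")
    TRUE
  }
)

#' Construct a VolumeImage
#'
#' @param data numeric 3D array with dim (nz, ny, nx)
#' @param voxelSize numeric length-3 voxel size in micrometres, order (z, y, x)
#' @return a \code{VolumeImage}
#' @export
VolumeImage <- function(data, voxelSize = DEFAULT_VOXEL_SIZE) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  vs <- as.numeric(voxelSize)
  names(vs) <- c("z", "y", "x")
  new("VolumeImage", data = data, voxelSize = vs)
}

setClass("NucleusMask",
  representation(mask = "array", voxelSize = "numeric"),
  validity = function(object) {
    if (length(dim(object@mask)) != 3L)
      return("mask must be a 3D array")
    if (!is.logical(object@mask))
      return("mask must be logical")
    if (!any(object@mask))
      return("mask is empty")
    TRUE
  }
)

#' Construct a NucleusMask
#'
#' A binary 3D nuclear region of interest.  Validity requires a nonempty
#' mask; \code{segmentNucleus3D} additionally guarantees a single
#' 26-connected component.
#'
#' @param mask logical 3D array
#' @param voxelSize voxel size in micrometres (z, y, x)
#' @param checkConnected verify the mask is one 26-connected component
#' @return a \code{NucleusMask}
#' @export
NucleusMask <- function(mask, voxelSize = DEFAULT_VOXEL_SIZE,
                        checkConnected = TRUE) {
  storage.mode(mask) <- "logical"
  vs <- as.numeric(voxelSize)
  names(vs) <- c("z", "y", "x")
  obj <- new("NucleusMask", mask = mask, voxelSize = vs)
  if (checkConnected) {
    ncc <- maxLabel(cc_label3d_cpp(as.vector(mask), dim(mask), 26L))
    if (ncc != 1L)
      stop("nucleus mask must be a single 26-connected component (found ",
           ncc, ")")
  }
  obj
}

setClass("SpotLabelMap",
  representation(labels = "array", voxelSize = "numeric", table = "data.frame"),
  validity = function(object) {
    if (length(dim(object@labels)) != 3L)
      return("labels must be a 3D array")
    n <- nrow(object@table)
    present <- sort(unique(as.vector(object@labels)))
    present <- present[present > 0]
    if (length(present) && !identical(as.integer(present), seq_len(n)))
      return("labels must be contiguous 1..n and match the object table")
    TRUE
  }
)

setClass("CompactionMap",
  representation(classes = "array", voxelSize = "numeric", K = "integer",
                 classMeans = "numeric", classSigmas = "numeric",
                 classFractions = "numeric", beta = "numeric",
                 converged = "logical", iterations = "integer"),
  validity = function(object) {
    if (length(object@classMeans) != object@K)
      return("classMeans length must equal K")
    if (is.unsorted(object@classMeans, strictly = TRUE))
      return("class means must be strictly increasing with class label")
    fr <- object@classFractions
    if (length(fr) == object@K && abs(sum(fr) - 1) > 1e-8)
      return("class volume fractions must sum to 1")
    TRUE
  }
)

setClass("OriginSet",
  representation(peaks = "GRanges"),
  validity = function(object) {
    gr <- object@peaks
    if (length(gr) == 0) return(TRUE)
    if (any(GenomicRanges::width(gr) < 1))
      return("intervals must satisfy start < end")
    if (!S4Vectors::isSorted(gr))
      return("intervals must be sorted by (chrom, start)")
    TRUE
  }
)

# ---- accessors ----

setGeneric("imgData", function(x) standardGeneric("imgData"))
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
setGeneric("spotTable", function(x) standardGeneric("spotTable"))
setGeneric("nSpots", function(x) standardGeneric("nSpots"))
setGeneric("classArray", function(x) standardGeneric("classArray"))
setGeneric("classFractions", function(x) standardGeneric("classFractions"))
setGeneric("classMeans", function(x) standardGeneric("classMeans"))
setGeneric("originRanges", function(x) standardGeneric("originRanges"))
setGeneric("originMids", function(x) standardGeneric("originMids"))
setGeneric("originCount", function(x) standardGeneric("originCount"))

setMethod("imgData", "VolumeImage", function(x) x@data)
setMethod("voxelSize", "VolumeImage", function(x) x@voxelSize)
setMethod("voxelSize", "NucleusMask", function(x) x@voxelSize)
setMethod("voxelSize", "SpotLabelMap", function(x) x@voxelSize)
setMethod("voxelVolume", "VolumeImage", function(x) prod(x@voxelSize))
setMethod("voxelVolume", "NucleusMask", function(x) prod(x@voxelSize))
setMethod("voxelVolume", "SpotLabelMap", function(x) prod(x@voxelSize))
setMethod("maskArray", "NucleusMask", function(x) x@mask)
setMethod("labelArray", "SpotLabelMap", function(x) x@labels)
setMethod("spotTable", "SpotLabelMap", function(x) x@table)
setMethod("nSpots", "SpotLabelMap", function(x) nrow(x@table))
setMethod("classArray", "CompactionMap", function(x) x@classes)
setMethod("classFractions", "CompactionMap", function(x) x@classFractions)
setMethod("classMeans", "CompactionMap", function(x) x@classMeans)
setMethod("originRanges", "OriginSet", function(x) x@peaks)
setMethod("originCount", "OriginSet", function(x) length(x@peaks))

#' Interval midpoints (0-based coordinates)
#'
#' Midpoints are \code{floor((start + end) / 2)} of the 0-based half-open
#' interval, the convention used for inter-origin distances.
#' @param x an \code{OriginSet}
#' @export
setMethod("originMids", "OriginSet", function(x) {
  gr <- x@peaks
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  as.integer(floor((s0 + e0) / 2))
})

#' Compaction class grouping into nuclear compartments
#'
#' Class 1 is the interchromatin compartment (IC), classes 2-4 the active
#' nuclear compartment (ANC), and classes 5-7 the chromatin domain clusters
#' of the inactive nuclear compartment (CDC/INC).
#' @param K number of classes
#' @return named list of class index vectors
#' @export
classGrouping <- function(K = 7L) {
  if (K != 7L) {
    cut <- round(K * c(1, 4) / 7)
    return(list(IC = seq_len(max(1, cut[1])),
                ANC = seq(max(1, cut[1]) + 1, cut[2]),
                INC = seq(cut[2] + 1, K)))
  }
  list(IC = 1L, ANC = 2:4, INC = 5:7)
}

# ---- show methods ----

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeImage: %d x %d x %d voxels (z,y,x), voxel %s um\n",
              d[1], d[2], d[3],
              paste(signif(object@voxelSize, 3), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "NucleusMask", function(object) {
  cat(sprintf("NucleusMask: %s voxels in mask (%.1f um^3)\n",
              format(sum(object@mask), big.mark = ","),
              sum(object@mask) * prod(object@voxelSize)))
})

setMethod("show", "SpotLabelMap", function(object) {
  cat(sprintf("SpotLabelMap: %d objects, total volume %.2f um^3\n",
              nrow(object@table), sum(object@table$volume_um3)))
})

setMethod("show", "CompactionMap", function(object) {
  cat(sprintf("CompactionMap: %d classes, beta = %.2f, %s\n", object@K,
              object@beta,
              if (object@converged) "converged" else "not converged"))
  cat("  volume fractions:",
      paste(sprintf("%.3f", object@classFractions), collapse = " "), "\n")
})

setMethod("show", "OriginSet", function(object) {
  gr <- object@peaks
  cat(sprintf("OriginSet: %d intervals on %d chromosome(s)\n", length(gr),
              length(unique(as.character(GenomicRanges::seqnames(gr))))))
})

# largest label in an integer label vector (0 = background)
#' @keywords internal
maxLabel <- function(lab) {
  if (length(lab) == 0) return(0L)
  max(0L, max(lab))
}
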