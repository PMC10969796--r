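# TIFF stack input/output.  Stacks are stored one z-plane per page with the
# package's (z, y, x) array convention; intensities are scaled to the TIFF
# integer range on write and restored with the recorded scale on read.

#' Read a 3D TIFF stack into a VolumeImage
#'
#' @param path TIFF file (one z-plane per page)
#' @param voxelSize voxel size in micrometres (z, y, x)
#' @param scale multiply the [0, 1] pixel data by this factor (e.g. 65535
#'   to recover 16-bit counts)
#' @return a \code{VolumeImage}
#' @export
readVolumeTIFF <- function(path, voxelSize = DEFAULT_VOXEL_SIZE,
                           scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra samples
    p
  })
  d <- dim(pages[[1]])
  a <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) a[i, , ] <- pages[[i]]
  VolumeImage(a * scale, voxelSize)
}

#' Write a VolumeImage as a multi-page TIFF
#'
#' Intensities are divided by \code{scale} (default: the data maximum) and
#' written at the requested bit depth.
#'
#' @param volume a \code{VolumeImage}
#' @param path output file
#' @param bitsPerSample TIFF bit depth (8 or 16)
#' @param scale divisor mapping intensities into [0, 1]
#' @return the scale used, invisibly
#' @export
writeVolumeTIFF <- function(volume, path, bitsPerSample = 16L,
                            scale = NULL) {
  a <- imgData(volume)
  if (is.null(scale)) scale <- max(a, 1e-12)
  a <- pmin(pmax(a / scale, 0), 1)
  pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = bitsPerSample,
                  compression = "none")
  invisible(scale)
}
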