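#' Chromatin compaction classification
#'
#' Each in-mask voxel of the DAPI channel is assigned to one of K (default
#' 7) compaction classes with a Gaussian-emission hidden Markov random
#' field: class-conditional Gaussian intensities plus a Potts spatial
#' prior on the 6-neighbourhood.  Class 1 is the interchromatin
#' compartment (IC), classes 2-4 the active nuclear compartment (ANC) and
#' classes 5-7 the chromatin domain clusters of the inactive compartment
#' (CDC/INC).  Fitting is per nucleus, so staining differences between
#' samples do not bias the classes.
#'
#' @name compaction-module
NULL

#' Classify nuclear voxels into compaction classes (HMRF-EM/ICM)
#'
#' Classes are initialized from intensity quantiles and optimized by
#' alternating ICM label updates (deterministic, 6-neighbourhood Potts
#' prior at strength \code{beta}) with Gaussian parameter re-estimation,
#' until fewer than 0.1 percent of labels change or \code{maxIter} is
#' reached.  Classes are relabelled by ascending mean intensity, so the
#' label order always runs from IC to compact chromatin.  With
#' \code{beta = 0} the procedure reduces to a plain (classification-EM)
#' Gaussian mixture on intensities.
#'
#' @param dapi a \code{VolumeImage}
#' @param mask a \code{NucleusMask}
#' @param K number of classes
#' @param beta Potts prior strength (>= 0)
#' @param maxIter maximum EM iterations
#' @return a \code{CompactionMap}
#' @export
classifyCompaction <- function(dapi, mask, K = 7L, beta = 1.0,
                               maxIter = 50L) {
  if (K < 2L) stop("K must be >= 2")
  if (beta < 0) stop("beta must be >= 0")
  a <- imgData(dapi)
  m <- maskArray(mask)
  if (!identical(dim(a), dim(m))) stop("DAPI and mask shapes differ")
  v <- a[m]
  if (length(v) < 10 * K)
    stop(sprintf("only %d in-mask voxels; need at least %d for K = %d",
                 length(v), 10 * K, K))
  if (stats::sd(v) == 0)
    stop("constant in-mask intensity; compaction classes undefined")
  d <- dim(a)

  # affine-invariant working scale
  v01 <- (a - min(v)) / (max(v) - min(v))
  v01[!m] <- 0

  q <- stats::quantile(v01[m], probs = (seq_len(K) - 0.5) / K, names = FALSE)
  lab <- array(0L, d)
  lab[m] <- max.col(-abs(outer(v01[m], q, `-`)), ties.method = "first")

  mu <- sig <- numeric(K)
  nIn <- sum(m)
  changedFrac <- Inf
  it <- 0L
  converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    labIn <- lab[m]
    for (k in seq_len(K)) {
      sel <- labIn == k
      if (!any(sel)) {
        # re-seed an emptied class at the least-covered quantile
        mu[k] <- q[k]
        sig[k] <- 0.05
      } else {
        mu[k] <- mean(v01[m][sel])
        sig[k] <- max(stats::sd(v01[m][sel]), 1e-4)
        if (is.na(sig[k])) sig[k] <- 1e-4
      }
    }
    sw <- icm_sweep3d_cpp(as.vector(v01), as.vector(lab), d, K, mu, sig,
                          beta)
    lab <- array(sw$labels, d)
    changedFrac <- sw$changed / nIn
    if (changedFrac < 1e-3) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf(paste0("ICM did not converge in %d iterations ",
                           "(%.2f%% labels still changing); ",
                           "returning the current labelling"),
                    maxIter, 100 * changedFrac))

  # order classes by ascending mean intensity
  ord <- order(mu)
  relab <- integer(K)
  relab[ord] <- seq_len(K)
  labIn <- lab[m]
  lab[m] <- relab[labIn]
  muOut <- mu[ord]
  sigOut <- sig[ord]
  # enforce strict ordering for degenerate ties
  eps <- 1e-12 * seq_len(K)
  muOut <- muOut + ifelse(duplicated(muOut), eps, 0)

  fr <- tabulate(lab[m], nbins = K) / sum(m)
  new("CompactionMap", classes = lab, voxelSize = voxelSize(dapi),
      K = as.integer(K), classMeans = muOut, classSigmas = sigOut,
      classFractions = fr, beta = beta, converged = converged,
      iterations = it)
}

#' Intensity-weighted mapping of a signal to compaction classes
#'
#' Within the segmented signal mask, each voxel contributes its intensity
#' to the class it sits in; fractions are normalized by the total
#' in-mask signal, so brighter voxels weigh more.
#'
#' @param signal a \code{VolumeImage}
#' @param signalMask binary mask (or \code{SpotLabelMap}) of the
#'   segmented signal
#' @param compaction a \code{CompactionMap}
#' @return list with \code{fractions} (length K, summing to 1 when signal
#'   is present) and \code{zeroSignal} flag
#' @export
mapSignalToClasses <- function(signal, signalMask, compaction) {
  a <- imgData(signal)
  sm <- asBinaryArray(signalMask)
  cls <- classArray(compaction)
  if (!identical(dim(a), dim(sm)) || !identical(dim(a), dim(cls)))
    stop("signal, mask and compaction map shapes differ")
  K <- compaction@K
  sel <- sm & cls > 0
  tot <- sum(a[sel])
  if (tot <= 0)
    return(list(fractions = rep(0, K), zeroSignal = TRUE))
  w <- tapply(a[sel], factor(cls[sel], levels = seq_len(K)), sum)
  w[is.na(w)] <- 0
  list(fractions = as.numeric(w) / tot, zeroSignal = FALSE)
}
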