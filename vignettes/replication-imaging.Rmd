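---
title: "Quantifying genome replication progression in single cells"
author: "replikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genome replication progression in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replikit)
```

# Scope

`replikit` implements the image-analysis and interval-analysis side of
single-cell DNA replication studies that compare pluripotent and somatic
human cells: detection and characterization of replication foci (RFi) in
3D confocal or super-resolution stacks, repli-FISH replication timing of
repeat elements by binary-mask intersection, a ratiometric EdU/PCNA
fork-speed proxy, chromatin compaction classification of the DAPI signal,
and replication-origin interval statistics from SNS-seq peak files.  A
synthetic-data generator with planted ground truth ties the pieces
together and backs the test suite.

Wet-lab steps, microscope acquisition and deconvolution, live-cell
tracking, and upstream sequencing (read trimming, alignment, peak
calling) are out of scope; peak calling is expected to be done with the
usual external tools and fed in as BED/narrowPeak files.

# Data model

A channel of a 3D acquisition is a `VolumeImage`: a numeric array with
`dim = c(nz, ny, nx)` and a voxel size in micrometres, default
`0.29 x 0.125 x 0.125` (z, y, x), the geometry of a 100x confocal stack
acquired with a 300 nm z-interval.  All distances, volumes, and Gaussian
widths are computed in micrometres, honouring the anisotropy; voxel
indices never leak into measurements.  Derived objects are `NucleusMask`
(binary ROI, one 26-connected component), `SpotLabelMap` (labelled foci
with per-object volume, intensity-weighted centroid, and sum intensity),
`CompactionMap` (per-voxel class 1..K), and `OriginSet` (sorted 0-based
half-open genomic intervals wrapped around a `GRanges`).

# Cell-cycle profiling and durations

High-throughput 2D profiling sums each nucleus stack over z
(`projectSum`), segments nuclei with a classical detector — Gaussian
smoothing, Otsu threshold, distance-transform watershed, area filter
(`segmentNuclei2D`) — and measures per-nucleus DAPI and EdU intensities.
`gateCellCycle` assigns S phase to cells above an EdU threshold (Otsu on
`log1p(EdU)` by default, or manual) and splits the remainder into G1/G2
at the midpoint of the two dominant DAPI modes, i.e. the 1x and 2x
DNA-content peaks.  A distribution whose two main modes are closer than a
ratio of 1.3 is treated as unimodal and the automatic cutoff refuses with
advice to set a manual one, since a genuine G1/G2 pair sits near a ratio
of 2.  Automatic thresholds require at least 20 cells.  Whether EdU is
summarized per nucleus as a sum or a mean is configurable
(`measureNuclei2D`, default sum).

Durations follow from growth arithmetic: the doubling time of an
exponentially growing culture observed at two time points is
`dt = log(2) * deltaT / (log N2 - log N1)` (any log base), and a phase or
sub-stage lasts its population fraction times `dt`.  Fractions summing to
1 therefore conserve `dt` exactly.  Manual scoring of S sub-stage
patterns is accepted as an input column, not automated.

# 3D nucleus segmentation

`segmentNucleus3D` builds the nuclear ROI from DAPI: Gaussian smoothing
with a lateral sigma of 2 px and an axial sigma scaled by the voxel
anisotropy, min-max normalization, a global Otsu threshold, retention of
the largest 26-connected component, then `d` dilations, 3D hole filling,
and `e` erosions (`d = e = 2` by default, a net closing).  Because of the
normalization the mask is invariant to affine rescaling of the
intensities.  The exact structuring element and iteration counts of
published pipeline scripts are not fixed by any standard, so they are
exposed as parameters; the defaults are symmetric.  Instead of an
interactive check of awkward (e.g. cylindrical) nuclei, `maskQC` reports
volume, surface, sphericity, and extents.  `maskChannel` zeroes a channel
outside the mask, the 3D equivalent of an image-calculator "min" with the
binary mask.

# 3D spot segmentation

Spot detection and growth run on a mean-filtered (radius 1 px), min-max
normalized copy of the masked channel.  Seeds are 26-neighbourhood
regional maxima with two guards:

* a prominence (noise tolerance) `h`: a candidate is rejected when a
  flood over voxels within `h` of its value reaches a strictly higher
  voxel.  The default is 3x the robust noise sd, where noise is
  estimated on the raw volume from first differences
  (`mad/sqrt(2)`) and propagated through the mean filter's
  `1/sqrt(taps)` gain — estimating it after filtering would
  underestimate it badly because filtered noise is spatially correlated;
* a detection floor (default: in-mask median plus 6x that noise sd) so
  that the regional maxima of pure background noise cannot seed spots.
  Without a floor, the brightest background fluctuation in a volume of
  hundreds of thousands of voxels would always be reported as a "spot".

True 3D maxima were chosen over per-slice 2D maxima for rotational
consistency of the detector.

Each seed receives its own stopping threshold from a least-squares fit of
`I(r) = A exp(-r^2 / (2 sigma^2)) + B` to the radial mean profile around
it (0.5-voxel bins out to 10x the initial sigma guess, radii in
micrometres): the threshold is `A exp(-k^2/2) + B`, the intensity `k`
sigmas from the centre.  `k = 2` by default, i.e. about 13.5% of the
amplitude above background; `k` is the free parameter of the
segmentation and is exposed everywhere.  Non-convergent fits fall back to
the half-height `B + (A - B)/2` and are flagged.  Seeds grow over
26-connected voxels at or above their threshold; where grown regions
touch, a marker-based 3D watershed on the processed intensity (priority
flooding from the seeds) separates clustered foci.  Objects below 5
voxels are discarded as single-voxel noise.  Feature extraction reports
volumes (voxel count times voxel volume), all-pairs centroid distances,
and centroid-to-border distances, all in micrometres; border distance is
centroid-to-border rather than edge-to-edge, matching distances computed
from ROI centres (edge-to-edge is a documented alternative one can build
from the label map).

# Repli-FISH and colocalization

Replication timing of repeats uses the "AND" formalism: binary masks of
RFi and FISH signals are intersected voxelwise and the 26-connected
components of the intersection are the replicating repeat loci
(`andColocalize`, `replicatingRepeatCount`).  "Associated" in the triple
analysis with RNA polymerase I (RPA 194) means at least one shared voxel;
an optional dilation tolerance (default 0) absorbs registration slack,
since sequential hybridization is assumed perfectly registered.
`probeTimingProfile` normalizes per-cell probe-in-RFi sum intensities to
the median of the early-S (S I) cells of the same probe and cell line,
so fold change 1 is the early-S anchor; cells with zero probe-in-RFi
signal are kept as zeros by default (a `dropZero` flag removes them),
because dropping them silently would bias late-replicating probes.

# Fork-speed proxy

Per nucleus, the ratio of total EdU (incorporated nucleotides) to total
PCNA (active replisomes) tracks DNA synthesized per replisome.  The
default estimator sums background-subtracted intensities inside the
nuclear mask.  Two numerical choices matter and were validated on
planted data:

* background is the per-channel **mean** of in-mask voxels outside foci,
  with a single exclusion region shared by both channels (bright voxels
  of either channel, dilated).  A shared region keeps residual spot-tail
  contamination proportional between the channels, so it cancels in the
  ratio; a histogram-mode estimator is available but is markedly noisier
  at single-nucleus voxel counts, and per-channel exclusion regions
  break the cancellation;
* subtracted sums are **not** clipped at zero, so zero-mean noise
  residuals cancel instead of accumulating a positive bias.

A volume-based mode (ratio of segmented EdU to PCNA spot volumes) is
provided for the spatial "EdU inside PCNA" reading.  `normalizeRatios`
divides by the group median (default grouping: cell line across all
stages, enabling cross-stage comparison), which makes the statistic
invariant to global channel gains and fixes the group median at 1.

# Chromatin compaction classes

`classifyCompaction` fits a Gaussian-emission hidden Markov random field
to the in-mask DAPI intensities: K classes (default 7) with
class-specific means and variances, and a Potts prior of strength `beta`
(default 1.0) on the 6-neighbourhood.  Labels are initialized from
intensity quantiles and updated by sequential ICM sweeps alternating with
parameter re-estimation until fewer than 0.1% of labels change (or
`maxIter`).  ICM was chosen over stochastic sampling so classification is
deterministic.  Classes are relabelled by ascending mean, giving the
standard reading: class 1 is the interchromatin compartment (IC), classes
2-4 the active nuclear compartment (ANC), classes 5-7 the chromatin
domain clusters of the inactive compartment (CDC/INC)
(`classGrouping`).  Fitting is strictly per nucleus, which makes the
classes robust to staining differences between samples.  Intensities are
min-max normalized first, so the classification is affine-invariant.
With `beta = 0` the procedure reduces to a hard-assignment Gaussian
mixture, which the tests cross-check against an independent mixture
implementation.  `mapSignalToClasses` distributes a segmented signal
(e.g. RFi) over the classes weighted by voxel intensity, so brighter
voxels count more; profiles sum to 1 unless the signal is empty, which
is flagged rather than divided by zero.

# Origin interval analytics

`OriginSet`s come from BED or ENCODE narrowPeak files (0-based half-open;
malformed lines are reported by number).  `mergeOrigins` merges intervals
whose gap is at most the window — the distance-merge semantics of the
standard interval toolkits, so `window = 0` merges overlapping and
bookended intervals; the implementation delegates to
`GenomicRanges::reduce(min.gapwidth = window + 1)` and the tests compare
it against an independent quadratic union-find oracle.  Inter-origin
distances are successive midpoint differences strictly within
chromosomes, with `mid = floor((start + end)/2)`; the pooled mean and a
per-chromosome table are both reported.  Overlap between two sets counts
an interval as shared when it intersects the other set by at least 1 bp,
with no reciprocal-fraction requirement; because the two directional
percentages need not agree, both are returned along with a union-based
count for Euler-style reporting.  `clusterCountProfile` reports merged
set sizes at 10/20/30 kb by default, the windows used to compare origin
number variability across cell types.

# The synthetic-data generator

`simulateNucleus` emulates exactly the structure the analyses assume — it
is the ground-truth instrument of the package, not a renderer of
realistic micrographs:

* an ellipsoidal nucleus (default semi-axes 2.6 x 5 x 5 um on a
  24 x 96 x 96 grid at confocal voxel size) — real nuclei are neither
  perfectly ellipsoidal nor texture-free at the membrane;
* a DAPI channel whose intensity is a strictly increasing step function
  of a compaction-class field sampled from a K-state Potts model by 50
  fixed Gibbs sweeps (approximate spatial coupling is sufficient for
  recovery experiments; default `beta = 0.6`, a moderate clumping);
* spot channels with isotropic-in-micrometre Gaussian spots (default
  sigma 0.3 um, amplitude 100 over background 10) placed uniformly,
  peripherally, or in clusters, with a minimum pairwise separation
  (default 4 sigma).  For a colocalization pair, the stated fraction of
  probe spots is planted exactly at reference-spot centroids and the
  rest are kept at least the minimum separation away from every
  reference spot, so planted counts are exact;
* an EdU channel equal to `eduPcnaRatio` times the clean PCNA channel,
  making the planted fork-speed ratio exact before noise;
* Gaussian read noise (default sd 10, i.e. SNR 10 at the default
  amplitude) plus optional Poisson shot noise on the clean signal, the
  standard fluorescence model.

What the generator does **not** emulate: optics (no PSF or depth-dependent
blur beyond the spot sigma), chromatic shifts, bleaching, nucleoli, or
time series.  Passing tests therefore demonstrate the correctness of the
measurement machinery under the stated statistical model, not performance
on arbitrary real micrographs.  `simulatePopulation` plants exact phase
counts (largest-remainder rounding) with DAPI at 1x/2x DNA content and
EdU elevated only in S; `simulateOriginSet` plants origin peaks with
known midpoint gaps (log-normal by default, with a mean gap of 34.3 kb
as reported for unclustered pluripotent origin maps).

All generators accept one RNG seed and restore the global RNG state, so
identical specs are bit-identical and independent of call order.

# Problem sizes and validation

The suite and `scripts/acceptance.R` validate on: 20 nuclei of
24 x 96 x 96 voxels with 50 planted spots each (counts recovered exactly,
centroid error under one voxel); the closed-form Gaussian threshold
`100 e^{-2} + 10 = 23.53`; 100 random interval sets of up to 200
intervals against the quadratic merge oracle at windows 0/1/10/30 kb;
planted colocalization (8 of 20 probes), fork ratios 0.5/1/2 within 2%,
and 7-class HMRF recovery at 3-sigma class separation (about 90% voxel
accuracy over 10 nuclei).  These sizes keep the whole validation in the
minutes range on one CPU while leaving each statistic well away from
small-sample degeneracy.

# Known limitations

* The Gaussian radial-profile fit assumes approximately isotropic spots
  in micrometres; strongly elongated foci bias sigma and hence the
  stopping threshold toward the mean profile.
* The watershed assigns every above-threshold voxel to the seed reached
  along the highest-intensity path; for heavily overlapping spots the
  boundary placement, like all watershed variants, is heuristic.
* ICM converges to a local optimum; with very strong priors
  (`beta >> 1`) it can oversmooth fine IC structure.  The 0.1%
  label-change criterion, quantile initialization, and ascending-mean
  relabelling make results reproducible but not globally optimal.
* The fork-speed statistic is a proxy: it reports nucleotide
  incorporation per replisome signal, not fiber-level fork velocity.
* Sub-stage (S I/S II/S III) calls are taken as input labels; automatic
  pattern classification is deliberately out of scope.
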