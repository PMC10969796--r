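#' Pipeline configuration
#'
#' Bundles the voxel geometry, the channel-to-role mapping and all module
#' parameters for \code{\link{runPipeline}}.  Validation is eager: a
#' missing channel mapping fails here, before any computation.
#'
#' @param voxelSize voxel size in micrometres (z, y, x)
#' @param channels named character vector mapping roles to channel names;
#'   recognized roles: \code{dapi} (required), \code{foci}, \code{edu},
#'   \code{pcna}, \code{probe}, \code{rpa}
#' @param analyses subset of \code{c("foci", "forkspeed", "replifish",
#'   "compaction")}
#' @param k Gaussian-fit threshold parameter for spot segmentation
#' @param beta HMRF Potts strength for compaction classification
#' @param nClasses compaction classes
#' @param minVoxels minimum spot size in voxels
#' @param outDir optional output directory for CSV results and manifest
#' @param seed RNG seed recorded in the manifest
#' @return a validated list of class \code{"pipelineConfig"}
#' @export
pipelineConfig <- function(voxelSize = DEFAULT_VOXEL_SIZE,
                           channels = c(dapi = "DAPI", foci = "PCNA"),
                           analyses = "foci",
                           k = 2, beta = 1.0, nClasses = 7L,
                           minVoxels = 5L, outDir = NULL, seed = 1L) {
  if (any(voxelSize <= 0)) stop("voxel sizes must be positive")
  analyses <- match.arg(analyses,
                        c("foci", "forkspeed", "replifish", "compaction"),
                        several.ok = TRUE)
  need <- c("dapi")
  if (any(c("foci", "replifish") %in% analyses)) need <- c(need, "foci")
  if ("forkspeed" %in% analyses) need <- c(need, "edu", "pcna")
  if ("replifish" %in% analyses) need <- c(need, "probe")
  missing <- setdiff(need, names(channels))
  if (length(missing))
    stop("no channel mapped for role(s): ", paste(missing, collapse = ", "))
  cfg <- list(voxelSize = as.numeric(voxelSize), channels = channels,
              analyses = analyses, k = k, beta = beta,
              nClasses = as.integer(nClasses),
              minVoxels = as.integer(minVoxels), outDir = outDir,
              seed = as.integer(seed))
  class(cfg) <- "pipelineConfig"
  cfg
}

channelOf <- function(cell, cfg, role) {
  nm <- cfg$channels[[role]]
  if (is.null(nm) || !nm %in% names(cell))
    stop(sprintf("cell lacks channel '%s' for role '%s'", nm, role))
  cell[[nm]]
}

#' Run the per-cell analysis pipeline
#'
#' For every cell (a named list of \code{VolumeImage} channels), segments
#' the nucleus from the DAPI channel, masks the remaining channels, and
#' runs the configured analyses.  Per-cell failures are logged and
#' skipped; the run fails only if every cell fails.  With a fixed config
#' and seed, reruns are byte-identical.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @param cells list of cells; each a named list of \code{VolumeImage}s.
#'   Optional per-cell attributes \code{"stage"} and \code{"line"} are
#'   propagated to the result tables.
#' @return list of long-format data.frames (one per analysis) plus the
#'   run \code{manifest}
#' @export
runPipeline <- function(config, cells) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (length(cells) == 0) stop("no cells to analyse")
  if (is.null(names(cells)))
    names(cells) <- sprintf("cell%03d", seq_along(cells))
  set.seed(config$seed)

  rows <- list(foci = list(), forkspeed = list(), replifish = list(),
               compaction = list())
  failures <- character(0)

  for (id in names(cells)) {
    cell <- cells[[id]]
    stage <- attr(cell, "stage", exact = TRUE) %||% NA_character_
    line <- attr(cell, "line", exact = TRUE) %||% NA_character_
    res <- tryCatch({
      dapi <- channelOf(cell, config, "dapi")
      nucMask <- segmentNucleus3D(dapi)
      out <- list()
      spots <- NULL
      if (any(c("foci", "replifish") %in% config$analyses)) {
        fociCh <- maskChannel(channelOf(cell, config, "foci"), nucMask)
        spots <- segmentSpots(fociCh, mask = nucMask, k = config$k,
                              minVoxels = config$minVoxels)
        feats <- spotFeatures(spots, nucMask)
        out$foci <- data.frame(
          cell = id, stage = stage, line = line,
          n_spots = nSpots(spots),
          mean_volume_um3 = if (nSpots(spots)) mean(
            spotTable(spots)$volume_um3) else NA_real_,
          mean_pair_dist_um = if (nrow(feats$pairDistances)) mean(
            feats$pairDistances$distance_um) else NA_real_,
          mean_border_dist_um = if (nSpots(spots)) mean(
            feats$perSpot$border_dist_um) else NA_real_)
      }
      if ("forkspeed" %in% config$analyses) {
        fr <- forkRatio(maskChannel(channelOf(cell, config, "edu"), nucMask),
                        maskChannel(channelOf(cell, config, "pcna"),
                                    nucMask),
                        nucMask)
        out$forkspeed <- data.frame(cell = id, stage = stage, line = line,
                                    edu_total = fr$eduTotal,
                                    pcna_total = fr$pcnaTotal,
                                    ratio = fr$ratio)
      }
      if ("replifish" %in% config$analyses) {
        probeCh <- maskChannel(channelOf(cell, config, "probe"), nucMask)
        probeSpots <- segmentSpots(probeCh, mask = nucMask, k = config$k,
                                   minVoxels = config$minVoxels)
        cl <- andColocalize(probeSpots, spots)
        out$replifish <- data.frame(
          cell = id, stage = stage, line = line,
          n_probe = nSpots(probeSpots),
          n_replicating = cl$nObjects,
          probe_in_rfi = probeSignalInFoci(probeCh, spots))
      }
      if ("compaction" %in% config$analyses) {
        cmap <- classifyCompaction(dapi, nucMask, K = config$nClasses,
                                   beta = config$beta)
        out$compaction <- data.frame(
          cell = id, stage = stage, line = line,
          class = seq_len(config$nClasses),
          volume_fraction = classFractions(cmap))
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", id, conditionMessage(res)))
      next
    }
    for (nm in names(res)) rows[[nm]][[id]] <- res[[nm]]
  }

  if (length(failures) == length(cells))
    stop("all cells failed:\n", paste(failures, collapse = "\n"))
  if (length(failures))
    warning("skipped ", length(failures), " cell(s):\n",
            paste(failures, collapse = "\n"))

  tables <- lapply(rows, function(r) if (length(r)) do.call(rbind,
                                                            c(r, list(
    make.row.names = FALSE))) else NULL)
  tables <- tables[!vapply(tables, is.null, TRUE)]

  cfgForHash <- config
  cfgForHash$outDir <- NULL
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfgForHash), tf)
  manifest <- list(config = unclass(cfgForHash),
                   config_md5 = unname(tools::md5sum(tf)),
                   n_cells = length(cells),
                   n_failed = length(failures),
                   failures = failures,
                   r_version = as.character(getRversion()),
                   package_version = as.character(
                     utils::packageVersion("replikit")),
                   seed = config$seed)
  unlink(tf)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables))
      utils::write.csv(tables[[nm]],
                       file.path(config$outDir, paste0(nm, ".csv")),
                       row.names = FALSE)
    yaml::write_yaml(manifest, file.path(config$outDir, "manifest.yaml"))
  }
  c(tables, list(manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
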