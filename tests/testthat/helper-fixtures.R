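# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no binary fixtures.

# isotropic-in-um Gaussian spots rendered on an anisotropic grid, without
# going through the package generator (independent construction)
renderGaussians <- function(shape, voxelSize, centers, sigma, amplitude,
                            background = 0) {
  a <- array(background, shape)
  z <- (seq_len(shape[1]) - 0.5) * voxelSize[1]
  y <- (seq_len(shape[2]) - 0.5) * voxelSize[2]
  x <- (seq_len(shape[3]) - 0.5) * voxelSize[3]
  for (i in seq_len(nrow(centers))) {
    r2 <- outer(outer((z - centers[i, 1])^2, (y - centers[i, 2])^2, `+`),
                (x - centers[i, 3])^2, `+`)
    a <- a + amplitude * exp(-r2 / (2 * sigma^2))
  }
  a
}

# seed table accepted by segmentSpots, built from voxel positions
manualSeeds <- function(zyx, shape, proc = NULL) {
  idx <- (zyx[, 1] - 1L) + shape[1] * ((zyx[, 2] - 1L) +
                                       shape[2] * (zyx[, 3] - 1L)) + 1L
  df <- data.frame(z = zyx[, 1], y = zyx[, 2], x = zyx[, 3],
                   index = as.integer(idx),
                   value = if (is.null(proc)) NA_real_ else proc[idx])
  df
}

# Brute-force distance merge of 0-based half-open intervals: union-find on
# the all-pairs "gap <= window" adjacency (overlap counts as gap <= 0).
# Deliberately quadratic and independent of the package implementation.
bruteMergeOracle <- function(df, window) {
  out <- list()
  for (chrom in unique(df$chrom)) {
    s <- df$start[df$chrom == chrom]
    e <- df$end[df$chrom == chrom]
    n <- length(s)
    parent <- seq_len(n)
    findRoot <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    # all-pairs gap matrix (quadratic by construction)
    gap <- pmax(outer(s, s, pmax) - outer(e, e, pmin), -1)
    adj <- which(gap <= window & upper.tri(gap), arr.ind = TRUE)
    for (r in seq_len(nrow(adj))) {
      ri <- findRoot(adj[r, 1]); rj <- findRoot(adj[r, 2])
      if (ri != rj) parent[rj] <- ri
    }
    root <- vapply(seq_len(n), findRoot, 0L)
    for (r in unique(root)) {
      sel <- root == r
      out[[length(out) + 1]] <- data.frame(chrom = chrom,
                                           start = min(s[sel]),
                                           end = max(e[sel]))
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# all-pairs overlap count oracle (0-based half-open)
bruteOverlapOracle <- function(a, b) {
  hit <- 0L
  for (i in seq_len(nrow(a))) {
    any_hit <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          max(a$start[i], b$start[j]) < min(a$end[i], b$end[j]))
        any_hit <- TRUE
    }
    if (any_hit) hit <- hit + 1L
  }
  hit
}

randomIntervalSet <- function(n, chroms = c("chr1", "chr2")) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(2e5, n, replace = TRUE)
  width <- sample(50:2000, n, replace = TRUE)
  df <- data.frame(chrom = chrom, start = start, end = start + width)
  df[!duplicated(df[, c("chrom", "start", "end")]), , drop = FALSE]
}

originSetFromDf <- function(df) originSet(df$chrom, df$start, df$end)

originSetToDf <- function(os) {
  gr <- originRanges(os)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

# greedy matching of recovered to true centroids; returns nearest-match
# distances (um)
centroidMatchDist <- function(trueUm, foundUm) {
  stopifnot(nrow(trueUm) > 0, nrow(foundUm) > 0)
  vapply(seq_len(nrow(trueUm)), function(i) {
    sqrt(min(rowSums(sweep(foundUm, 2, trueUm[i, ])^2)))
  }, 0)
}
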