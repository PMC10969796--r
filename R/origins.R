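#' Replication-origin interval analytics
#'
#' Origin peak sets (e.g. SNS-seq narrow peaks) are held as sorted,
#' 0-based half-open genomic intervals.  Internally an \code{OriginSet}
#' wraps a \code{GRanges} (1-based closed); all user-facing coordinates and
#' the BED reader/writer use the 0-based half-open convention.
#'
#' @name origins-module
NULL

#' Construct an OriginSet from 0-based half-open intervals
#'
#' @param chrom character chromosome names
#' @param start,end 0-based half-open interval bounds, \code{start < end}
#' @return an \code{OriginSet}, sorted by (chrom, start)
#' @export
originSet <- function(chrom = character(0), start = integer(0),
                      end = integer(0)) {
  if (length(start) != length(end) || length(chrom) != length(start))
    stop("chrom, start and end must have equal length")
  if (length(start) == 0)
    return(new("OriginSet", peaks = GenomicRanges::GRanges()))
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop(sprintf("interval %d has start >= end (%d >= %d)", bad,
                 start[bad], end[bad]))
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start + 1L,
                                                end = end))
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  gr <- GenomicRanges::sort(gr)
  if (any(duplicated(gr)))
    gr <- unique(gr)
  new("OriginSet", peaks = gr)
}

#' Read an origin peak file (BED or ENCODE narrowPeak)
#'
#' Accepts 3+ column BED or 10-column narrowPeak; extra columns beyond the
#' interval are ignored for the analytics.  Malformed lines are reported
#' with their line number.
#'
#' @param path file path
#' @return an \code{OriginSet}
#' @export
readPeaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(originSet())
  parts <- strsplit(lines, "\t| +")
  nf <- lengths(parts)
  if (any(nf < 3)) {
    bad <- which(nf < 3)[1]
    stop(sprintf("line %d: fewer than 3 fields", bad))
  }
  chrom <- vapply(parts, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("line %d: non-numeric interval bounds", bad))
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop(sprintf("line %d: start >= end (%d >= %d)", bad, start[bad],
                 end[bad]))
  }
  originSet(chrom, start, end)
}

#' Write an OriginSet as BED (0-based half-open)
#'
#' @param x an \code{OriginSet}
#' @param path output path
#' @export
writePeaksBED <- function(x, path) {
  gr <- originRanges(x)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge origins within a distance window
#'
#' Intervals on the same chromosome whose gap is at most \code{window} bp
#' are merged into their span (the distance-based merge of the standard
#' interval toolkits; \code{window = 0} merges overlapping and bookended
#' intervals).  The result is sorted and non-overlapping, with all pairwise
#' gaps greater than \code{window}.
#'
#' @param x an \code{OriginSet}
#' @param window merge distance in bp (>= 0)
#' @return merged \code{OriginSet}
#' @export
mergeOrigins <- function(x, window = 0L) {
  if (window < 0) stop("window must be >= 0")
  gr <- originRanges(x)
  if (length(gr) == 0) return(x)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = window + 1L)
  new("OriginSet", peaks = GenomicRanges::sort(merged))
}

#' Inter-origin distances (IOD)
#'
#' Distances between the midpoints of consecutive peaks, strictly within
#' chromosomes; the mean and median pool gaps across chromosomes.
#'
#' @param x an \code{OriginSet}
#' @return list with \code{gaps} (per-chromosome list), \code{perChrom}
#'   summary data.frame, and pooled \code{mean}, \code{median}, \code{n}
#' @export
interOriginDistances <- function(x) {
  gr <- originRanges(x)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  mids <- originMids(x)
  gaps <- lapply(split(mids, chrom), function(m) diff(sort(m)))
  pooled <- unlist(gaps, use.names = FALSE)
  if (length(pooled) && any(pooled <= 0))
    warning("duplicate midpoints produce zero-length gaps")
  perChrom <- data.frame(
    chrom = names(gaps),
    n_peaks = as.integer(table(chrom)[names(gaps)]),
    n_gaps = lengths(gaps),
    mean_iod = vapply(gaps, function(g) if (length(g)) mean(g) else NA_real_,
                      0),
    median_iod = vapply(gaps, function(g) if (length(g)) median(g) else
                          NA_real_, 0),
    row.names = NULL)
  list(gaps = gaps, perChrom = perChrom,
       mean = if (length(pooled)) mean(pooled) else NA_real_,
       median = if (length(pooled)) median(pooled) else NA_real_,
       n = length(pooled))
}

#' Overlap statistics between two origin sets
#'
#' An interval of one set is "shared" if it intersects at least one
#' interval of the other by >= 1 bp (half-open semantics, no reciprocal
#' fraction requirement).  Percentages are direction-dependent; the
#' union-based count supports Euler-style reporting.
#'
#' @param a,b \code{OriginSet}s
#' @return list with counts and percentages in both directions and for the
#'   merged union
#' @export
originOverlap <- function(a, b) {
  ga <- originRanges(a)
  gb <- originRanges(b)
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  sharedAB <- sum(GenomicRanges::countOverlaps(ga, gb) > 0)
  sharedBA <- sum(GenomicRanges::countOverlaps(gb, ga) > 0)
  un <- GenomicRanges::reduce(c(ga, gb))
  common <- sum(GenomicRanges::countOverlaps(un, ga) > 0 &
                GenomicRanges::countOverlaps(un, gb) > 0)
  list(n_a = length(ga), n_b = length(gb),
       shared_a_in_b = sharedAB, shared_b_in_a = sharedBA,
       pct_a_in_b = if (length(ga)) 100 * sharedAB / length(ga) else NA_real_,
       pct_b_in_a = if (length(gb)) 100 * sharedBA / length(gb) else NA_real_,
       n_union = length(un), n_common = common,
       pct_union_common = if (length(un)) 100 * common / length(un) else
         NA_real_)
}

#' Origin counts after clustering at increasing distance windows
#'
#' Counts the merged-set size at each window (default 10/20/30 kb), the
#' summary used to compare origin-number variability between cell types.
#'
#' @param x an \code{OriginSet}
#' @param windows merge windows in bp, ascending
#' @return data.frame with columns \code{window} and \code{n_origins}
#' @export
clusterCountProfile <- function(x, windows = c(10e3, 20e3, 30e3)) {
  if (is.unsorted(windows)) stop("windows must be sorted ascending")
  counts <- vapply(windows, function(w) originCount(mergeOrigins(x, w)), 0L)
  data.frame(window = windows, n_origins = counts)
}
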