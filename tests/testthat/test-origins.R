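test_that("peak files are read, sorted and validated", {
  empty <- tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_equal(originCount(readPeaks(empty)), 0L)

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr2\t500\t700", "chr1\t100\t200", "chr1\t10\t50"), bed)
  os <- readPeaks(bed)
  df <- originSetToDf(os)
  expect_equal(nrow(df), 3L)
  expect_equal(df$start, c(10L, 100L, 500L))

  np <- tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t10\t50\tpeak1\t100\t.\t5.2\t10.1\t8.7\t20",
               "chr1\t100\t200\tpeak2\t90\t.\t4.1\t9.0\t7.2\t50"), np)
  bed2 <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t50", "chr1\t100\t200"), bed2)
  expect_identical(originSetToDf(readPeaks(np)),
                   originSetToDf(readPeaks(bed2)))

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t50", "chr1\t300\t200"), bad)
  expect_error(readPeaks(bad), "line 2")
})

test_that("BED round-trip preserves 0-based half-open intervals", {
  os <- simulateOriginSet(c(chr1 = 10L, chr2 = 4L), seed = 3)$origins
  p <- tempfile(fileext = ".bed")
  writePeaksBED(os, p)
  expect_identical(originSetToDf(readPeaks(p)), originSetToDf(os))
})

test_that("distance merging matches the hand-worked example and is idempotent", {
  os <- originSet(rep("chr1", 3), c(0L, 150L, 500L), c(100L, 200L, 600L))
  m0 <- mergeOrigins(os, 0)
  expect_identical(originSetToDf(m0), originSetToDf(os))
  m100 <- mergeOrigins(os, 100)
  expect_equal(originSetToDf(m100),
               data.frame(chrom = c("chr1", "chr1"), start = c(0L, 500L),
                          end = c(200L, 600L)))
  expect_identical(originSetToDf(mergeOrigins(m100, 100)),
                   originSetToDf(m100))
  expect_error(mergeOrigins(os, -5), ">= 0")
})

test_that("merging agrees with the brute-force O(n^2) oracle", {
  set.seed(99)
  for (rep in 1:12) {
    df <- randomIntervalSet(sample(5:120, 1))
    os <- originSetFromDf(df)
    for (w in c(0, 1000, 10000)) {
      got <- originSetToDf(mergeOrigins(os, w))
      oracle <- bruteMergeOracle(originSetToDf(os), w)
      rownames(got) <- rownames(oracle) <- NULL
      expect_equal(got, oracle, info = sprintf("rep %d window %d", rep, w))
    }
  }
})

test_that("inter-origin distances pool per-chromosome midpoint gaps", {
  one <- originSet(c("chr1", "chr2"), c(100L, 900L), c(200L, 1000L))
  iod1 <- interOriginDistances(one)
  expect_equal(iod1$n, 0L)

  os <- originSet(rep("chr1", 3), c(50L, 350L, 950L), c(150L, 450L, 1050L))
  iod <- interOriginDistances(os)
  expect_equal(unname(iod$gaps$chr1), c(300, 600))
  expect_equal(iod$mean, 450)
  expect_equal(iod$n, 2L)

  # merging removes small gaps, so the mean IOD can only grow
  big <- simulateOriginSet(c(chr1 = 80L, chr2 = 60L), meanGap = 20000,
                           seed = 11)$origins
  expect_gte(interOriginDistances(mergeOrigins(big, 10000))$mean,
             interOriginDistances(big)$mean)
})

test_that("overlap statistics match hand counts and the all-pairs oracle", {
  a <- originSet(c("chr1", "chr1"), c(0L, 20L), c(10L, 30L))
  b <- originSet(c("chr1", "chr1"), c(5L, 100L), c(8L, 110L))
  ov <- originOverlap(a, b)
  expect_equal(ov$shared_a_in_b, 1L)
  expect_equal(ov$pct_a_in_b, 50)
  expect_equal(ov$shared_b_in_a, 1L)

  ident <- originOverlap(a, a)
  expect_equal(ident$pct_a_in_b, 100)
  expect_equal(ident$pct_b_in_a, 100)

  disj <- originOverlap(a, originSet("chr2", 0L, 10L))
  expect_equal(disj$shared_a_in_b, 0L)

  set.seed(7)
  for (rep in 1:8) {
    da <- randomIntervalSet(sample(5:60, 1))
    db <- randomIntervalSet(sample(5:60, 1))
    oa <- originSetFromDf(da); ob <- originSetFromDf(db)
    ov <- originOverlap(oa, ob)
    expect_equal(ov$shared_a_in_b,
                 bruteOverlapOracle(originSetToDf(oa), originSetToDf(ob)))
    expect_equal(ov$shared_b_in_a,
                 bruteOverlapOracle(originSetToDf(ob), originSetToDf(oa)))
  }
})

test_that("cluster-count profile is monotone and matches generator truth", {
  expect_equal(clusterCountProfile(originSet())$n_origins, c(0L, 0L, 0L))

  gen <- simulateOriginSet(c(chr1 = 60L), gaps = rep(c(5000, 15000, 25000),
                                                     length.out = 59),
                           seed = 13)
  prof <- clusterCountProfile(gen$origins, windows = c(10e3, 20e3, 30e3))
  # truth: gaps <= w merge; count = 1 + number of gaps > w
  g <- gen$truth$chr1$gaps
  expect_equal(prof$n_origins, vapply(c(10e3, 20e3, 30e3),
                                      function(w) sum(g > w) + 1L, 0L))
  expect_true(all(diff(prof$n_origins) <= 0))
  expect_error(clusterCountProfile(gen$origins, windows = c(2, 1)),
               "ascending")
})
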