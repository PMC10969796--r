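test_that("empty spot request yields blank channels and empty truth", {
  spec <- nucleusSimSpec(nSpots = c(PCNA = 0L), nClasses = 1, seed = 1,
                         noiseSd = 0, poissonNoise = FALSE)
  sim <- simulateNucleus(spec)
  expect_equal(nrow(sim$truth$spots), 0L)
  a <- imgData(sim$channels$PCNA)
  expect_true(all(a == spec$background))
})

test_that("planted spots are counted, inside the nucleus, and separated", {
  spec <- nucleusSimSpec(nSpots = c(PCNA = 50L), nClasses = 1, seed = 1)
  sim <- simulateNucleus(spec)
  tt <- sim$truth$spots
  expect_equal(nrow(tt), 50L)
  # all centroids inside the ellipsoid
  ctr <- spec$shape * spec$voxelSize / 2
  q <- ((tt$z_um - ctr[1]) / spec$semiAxes[1])^2 +
       ((tt$y_um - ctr[2]) / spec$semiAxes[2])^2 +
       ((tt$x_um - ctr[3]) / spec$semiAxes[3])^2
  expect_true(all(q <= 1))
  # pairwise separation respects the 4 sigma default
  d <- as.matrix(dist(tt[, c("z_um", "y_um", "x_um")]))
  diag(d) <- Inf
  expect_true(min(d) >= 4 * spec$spotSigma - 1e-9)
})

test_that("full colocalization forces shared centroids", {
  spec <- nucleusSimSpec(nSpots = c(FISH = 10L, PCNA = 30L),
                         colocPair = c("FISH", "PCNA"),
                         colocFraction = 1, nClasses = 1, seed = 6)
  sim <- simulateNucleus(spec)
  tt <- sim$truth$spots
  f <- as.matrix(tt[tt$channel == "FISH", c("z_um", "y_um", "x_um")])
  p <- as.matrix(tt[tt$channel == "PCNA", c("z_um", "y_um", "x_um")])
  shared <- apply(f, 1, function(r) min(rowSums(sweep(p, 2, r)^2)) < 1e-18)
  expect_true(all(shared))
  expect_equal(sim$truth$colocCount, 10L)
})

test_that("identical seeds give bit-identical output; seeds differ otherwise", {
  spec <- nucleusSimSpec(nSpots = c(PCNA = 10L), seed = 42)
  s1 <- simulateNucleus(spec)
  s2 <- simulateNucleus(spec)
  expect_identical(imgData(s1$channels$DAPI), imgData(s2$channels$DAPI))
  expect_identical(s1$truth$spots, s2$truth$spots)
  spec3 <- nucleusSimSpec(nSpots = c(PCNA = 10L), seed = 43)
  s3 <- simulateNucleus(spec3)
  expect_false(identical(imgData(s1$channels$PCNA),
                         imgData(s3$channels$PCNA)))
})

test_that("noiseless DAPI class means increase strictly with class label", {
  spec <- nucleusSimSpec(shape = c(12L, 40L, 40L),
                         semiAxes = c(1.6, 2.2, 2.2), nSpots = c(),
                         nClasses = 7, beta = 0.8, noiseSd = 0,
                         poissonNoise = FALSE, seed = 9)
  sim <- simulateNucleus(spec)
  cls <- sim$truth$classField[sim$mask]
  dapi <- imgData(sim$channels$DAPI)[sim$mask]
  mns <- tapply(dapi, cls, mean)
  expect_true(all(diff(mns) > 0))
})

test_that("ground-truth count equals maxima of the noiseless spot field", {
  spec <- nucleusSimSpec(nSpots = c(PCNA = 30L), nClasses = 1, seed = 2,
                         noiseSd = 0, poissonNoise = FALSE, background = 0)
  sim <- simulateNucleus(spec)
  seeds <- detectSeeds(sim$channels$PCNA,
                       mask = NucleusMask(sim$mask, spec$voxelSize,
                                          checkConnected = FALSE),
                       h = 0.1, floor = 0.2)
  expect_equal(nrow(seeds), 30L)
})

test_that("impossible placement reports the failed spot count", {
  spec <- nucleusSimSpec(nSpots = c(PCNA = 500L), nClasses = 1, seed = 1,
                         minSeparation = 3)
  expect_error(simulateNucleus(spec), "could not place")
})

test_that("population generator plants exact phase counts", {
  pop <- simulatePopulation(n = 500, fractions = c(G1 = 0.4, S = 0.4,
                                                   G2 = 0.2), seed = 7)
  expect_equal(unname(pop$truth$counts), c(200L, 200L, 100L))
  expect_equal(nrow(pop$cells), 500L)
  ph <- pop$truth$phase$phase
  # G2 DAPI roughly twice G1
  ratio <- mean(pop$cells$dapi[ph == "G2"]) / mean(pop$cells$dapi[ph ==
                                                                  "G1"])
  expect_lt(abs(ratio - 2), 0.1)
  # EdU positive only in S
  expect_gt(min(pop$cells$edu[ph == "S"]),
            max(pop$cells$edu[ph != "S"]))
})

test_that("all-G1 population is EdU negative", {
  pop <- simulatePopulation(n = 50, fractions = c(G1 = 1, S = 0, G2 = 0),
                            seed = 3)
  expect_true(all(pop$truth$phase$phase == "G1"))
  expect_lt(max(pop$cells$edu), 100)
  expect_error(simulatePopulation(fractions = c(G1 = -0.1, S = 0.6,
                                                G2 = 0.5)),
               "non-negative")
})

test_that("origin generator records true gaps and honours the seed", {
  one <- simulateOriginSet(c(chr1 = 1L), seed = 1)
  expect_length(one$truth$chr1$gaps, 0)
  fx <- simulateOriginSet(c(chr1 = 3L), gaps = c(300, 600), seed = 1)
  expect_equal(fx$truth$chr1$gaps, c(300, 600))
  expect_equal(mean(fx$truth$chr1$gaps), 450)
  a <- simulateOriginSet(c(chr1 = 20L), seed = 5)
  b <- simulateOriginSet(c(chr1 = 20L), seed = 5)
  c <- simulateOriginSet(c(chr1 = 20L), seed = 6)
  expect_identical(originSetToDf(a$origins), originSetToDf(b$origins))
  expect_false(identical(originSetToDf(a$origins), originSetToDf(c$origins)))
  # sorted, non-overlapping
  df <- originSetToDf(a$origins)
  expect_true(all(diff(df$start) > 0))
  expect_true(all(df$start[-1] >= df$end[-nrow(df)]))
})

test_that("spec validation rejects bad parameters", {
  expect_error(nucleusSimSpec(colocFraction = 1.2), "\\[0, 1\\]")
  expect_error(nucleusSimSpec(spotSigma = 0), "positive")
  expect_error(nucleusSimSpec(eduPcnaRatio = -1), "> 0")
})
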