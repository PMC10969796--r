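vsIso <- c(0.2, 0.2, 0.2)

test_that("blank volumes yield no seeds and an empty label map", {
  blank <- VolumeImage(array(0, c(8, 16, 16)))
  expect_equal(nrow(detectSeeds(blank)), 0L)
  sm <- segmentSpots(blank)
  expect_equal(nSpots(sm), 0L)
  expect_true(all(labelArray(sm) == 0))
})

test_that("well-separated planted spots are detected with full recall", {
  spec <- nucleusSimSpec(nSpots = c(PCNA = 50L), nClasses = 1, seed = 11)
  sim <- simulateNucleus(spec)
  nm <- NucleusMask(sim$mask, spec$voxelSize, checkConnected = FALSE)
  seeds <- detectSeeds(maskChannel(sim$channels$PCNA, nm), mask = nm)
  expect_equal(nrow(seeds), 50L)
  # recall and precision 1: every seed within 2 voxels of a unique truth spot
  tt <- sim$truth$spots
  seedUm <- cbind((seeds$z - 0.5) * spec$voxelSize[1],
                  (seeds$y - 0.5) * spec$voxelSize[2],
                  (seeds$x - 0.5) * spec$voxelSize[3])
  d <- centroidMatchDist(as.matrix(tt[, c("z_um", "y_um", "x_um")]), seedUm)
  expect_true(all(d < 2 * max(spec$voxelSize)))
})

test_that("noise tolerance h separates true and spurious maxima", {
  # low SNR on purpose: a vanishing tolerance accepts every noise bump on
  # the spot flank, a tolerance calibrated above the noise keeps one peak
  set.seed(21)
  shape <- c(20L, 40L, 40L)
  ctr <- matrix(shape * vsIso / 2, 1)
  clean <- renderGaussians(shape, vsIso, ctr, sigma = 0.35, amplitude = 100)
  noisy <- clean + rnorm(length(clean), sd = 20)
  v <- VolumeImage(noisy, vsIso)
  tiny <- detectSeeds(v, h = 1e-4, floor = 0.35)
  calib <- detectSeeds(v, h = 0.2, floor = 0.35)
  expect_gt(nrow(tiny), 1L)
  expect_equal(nrow(calib), 1L)
})

test_that("gaussian fit threshold matches the closed form", {
  shape <- c(40L, 80L, 80L)
  vs <- c(0.29, 0.125, 0.125)
  ctr <- matrix(shape * vs / 2, 1)
  a <- renderGaussians(shape, vs, ctr, sigma = 2, amplitude = 100,
                       background = 10)
  v <- VolumeImage(a, vs)
  seed <- round(shape / 2)
  ft <- gaussianFitThreshold(v, seed, k = 2, sigmaGuess = 2)
  expect_false(ft$fallback)
  expect_lt(abs(ft$threshold - (100 * exp(-2) + 10)), 0.5)
  # fitted sigma within 5% of the planted value
  expect_lt(abs(ft$sigma - 2) / 2, 0.05)
})

test_that("flat profiles fall back to the half-height threshold", {
  flat <- array(5, c(10, 20, 20))
  ft <- gaussianFitThreshold(flat, c(5, 10, 10), voxelSize = vsIso)
  expect_true(ft$fallback)
  expect_equal(ft$threshold, 5)
})

test_that("planted spots are segmented with sub-voxel centroid error", {
  spec <- nucleusSimSpec(nSpots = c(PCNA = 50L), nClasses = 1, seed = 12)
  sim <- simulateNucleus(spec)
  nm <- NucleusMask(sim$mask, spec$voxelSize, checkConnected = FALSE)
  sm <- segmentSpots(maskChannel(sim$channels$PCNA, nm), mask = nm)
  expect_equal(nSpots(sm), 50L)
  tt <- sim$truth$spots
  d <- centroidMatchDist(as.matrix(tt[, c("z_um", "y_um", "x_um")]),
                         as.matrix(spotTable(sm)[, c("z_um", "y_um",
                                                     "x_um")]))
  expect_true(all(d < min(spec$voxelSize)))
})

test_that("watershed splits a close spot pair that merges without it", {
  shape <- c(16L, 32L, 32L)
  sigma <- 0.4
  ctr <- shape * vsIso / 2
  sep <- 2 * sigma
  centers <- rbind(ctr + c(0, -sep / 2, 0), ctr + c(0, sep / 2, 0))
  a <- renderGaussians(shape, vsIso, centers, sigma, amplitude = 100)
  v <- VolumeImage(a, vsIso)
  zyx <- cbind(round(centers[, 1] / vsIso[1]), round(centers[, 2] /
                                                     vsIso[2]),
               round(centers[, 3] / vsIso[3]))
  proc <- replikit:::processSpotVolume(v, 1L)
  seeds <- manualSeeds(zyx, shape, proc)
  merged <- segmentSpots(v, seeds, watershed = FALSE)
  split <- segmentSpots(v, seeds, watershed = TRUE)
  expect_equal(nSpots(merged), 1L)
  expect_equal(nSpots(split), 2L)
})

test_that("total labelled volume shrinks as k decreases", {
  spec <- nucleusSimSpec(nSpots = c(PCNA = 20L), nClasses = 1, seed = 13)
  sim <- simulateNucleus(spec)
  nm <- NucleusMask(sim$mask, spec$voxelSize, checkConnected = FALSE)
  ch <- maskChannel(sim$channels$PCNA, nm)
  vols <- vapply(c(1, 1.5, 2), function(k)
    sum(spotTable(segmentSpots(ch, mask = nm, k = k))$volume_um3), 0)
  expect_true(all(diff(vols) >= 0))
})

test_that("spot features: pairwise and border distances in micrometres", {
  # two point spots at a 3-4-5 triangle distance
  shape <- c(30L, 50L, 30L)
  vs <- c(0.2, 0.2, 0.2)
  lab <- array(0L, shape)
  # centroids at (2,2,2) and (5,6,2) um -> distance 5 um
  p1 <- c(10L, 10L, 10L); p2 <- c(25L, 30L, 10L)
  lab[p1[1], p1[2], p1[3]] <- 1L
  lab[p2[1], p2[2], p2[3]] <- 2L
  tab <- data.frame(label = 1:2, n_voxels = 1L, volume_um3 = prod(vs),
                    z_um = c((p1[1] - 0.5) * 0.2, (p2[1] - 0.5) * 0.2),
                    y_um = c((p1[2] - 0.5) * 0.2, (p2[2] - 0.5) * 0.2),
                    x_um = c((p1[3] - 0.5) * 0.2, (p2[3] - 0.5) * 0.2),
                    sum_intensity = 1, seed = NA_integer_,
                    threshold = NA_real_, fallback = NA)
  sm <- new("SpotLabelMap", labels = lab, voxelSize = vs, table = tab)
  mask <- NucleusMask(array(TRUE, shape), vs, checkConnected = FALSE)
  ft <- spotFeatures(sm, mask)
  expect_equal(nrow(ft$pairDistances), 1L)
  expect_equal(ft$pairDistances$distance_um, 5)

  # single spot at the centre of a 10 um cube: border distance 5 um
  cube <- array(TRUE, c(50L, 50L, 50L))
  vs2 <- c(0.2, 0.2, 0.2)
  lab2 <- array(0L, dim(cube)); lab2[25, 25, 25] <- 1L
  tab2 <- tab[1, ]; tab2$z_um <- tab2$y_um <- tab2$x_um <- 5
  sm2 <- new("SpotLabelMap", labels = lab2, voxelSize = vs2, table = tab2)
  ft2 <- spotFeatures(sm2, NucleusMask(cube, vs2, checkConnected = FALSE))
  expect_lt(abs(ft2$perSpot$border_dist_um - 5), 0.15)

  # 3 spots -> exactly 3 pair distances
  tab3 <- rbind(tab, tab[1, ])
  tab3$label <- 1:3; tab3$z_um[3] <- 4
  lab3 <- lab; lab3[20, 20, 20] <- 3L
  sm3 <- new("SpotLabelMap", labels = lab3, voxelSize = vs, table = tab3)
  expect_equal(nrow(spotFeatures(sm3, mask)$pairDistances), 3L)
})

test_that("distances scale linearly with an isotropic grid scale", {
  spec <- nucleusSimSpec(nSpots = c(PCNA = 8L), nClasses = 1, seed = 14,
                         noiseSd = 0, poissonNoise = FALSE, background = 0)
  sim <- simulateNucleus(spec)
  nm <- NucleusMask(sim$mask, spec$voxelSize, checkConnected = FALSE)
  sm <- segmentSpots(maskChannel(sim$channels$PCNA, nm), mask = nm)
  ft <- spotFeatures(sm, nm)
  sc <- 2.5
  sm2 <- new("SpotLabelMap", labels = labelArray(sm),
             voxelSize = voxelSize(sm) * sc, table = {
               tb <- spotTable(sm)
               tb$z_um <- tb$z_um * sc; tb$y_um <- tb$y_um * sc
               tb$x_um <- tb$x_um * sc
               tb$volume_um3 <- tb$volume_um3 * sc^3
               tb
             })
  nm2 <- NucleusMask(maskArray(nm), voxelSize(nm) * sc,
                     checkConnected = FALSE)
  ft2 <- spotFeatures(sm2, nm2)
  expect_equal(ft2$pairDistances$distance_um,
               sc * ft$pairDistances$distance_um)
})

test_that("wider blur inflates the mean segmented spot volume", {
  # confocal vs super-resolution emulation
  spec <- nucleusSimSpec(nSpots = c(PCNA = 15L), nClasses = 1, seed = 15,
                         noiseSd = 0, poissonNoise = FALSE, background = 0)
  sim <- simulateNucleus(spec)
  nm <- NucleusMask(sim$mask, spec$voxelSize, checkConnected = FALSE)
  sharp <- maskChannel(sim$channels$PCNA, nm)
  blurred <- VolumeImage(replikit:::gaussFilter3d(imgData(sharp),
                                                  c(1.5, 3, 3)),
                         spec$voxelSize)
  vSharp <- mean(spotTable(segmentSpots(sharp, mask = nm))$volume_um3)
  vBlur <- mean(spotTable(segmentSpots(blurred, mask = nm))$volume_um3)
  expect_gte(vBlur, vSharp)
})
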