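compactionFixture <- function(seed, beta = 0.8, noiseSd = 10,
                              shape = c(16L, 48L, 48L)) {
  spec <- nucleusSimSpec(shape = shape, semiAxes = c(2, 2.6, 2.6),
                         nSpots = c(), nClasses = 7, beta = beta,
                         noiseSd = noiseSd, poissonNoise = FALSE,
                         seed = seed)
  sim <- simulateNucleus(spec)
  list(sim = sim,
       mask = NucleusMask(sim$mask, spec$voxelSize, checkConnected = FALSE))
}

test_that("a noiseless 7-level field is classified perfectly", {
  fx <- compactionFixture(seed = 31, noiseSd = 0)
  cm <- classifyCompaction(fx$sim$channels$DAPI, fx$mask, K = 7,
                           beta = 0.8)
  acc <- mean(classArray(cm)[fx$sim$mask] ==
              fx$sim$truth$classField[fx$sim$mask])
  expect_equal(acc, 1.0)
  expect_true(all(diff(classMeans(cm)) > 0))
})

test_that("Potts-coupled noisy fields are recovered above 90 percent", {
  fx <- compactionFixture(seed = 32)   # class separation 3 sigma
  cm <- classifyCompaction(fx$sim$channels$DAPI, fx$mask, K = 7,
                           beta = 0.8)
  acc <- mean(classArray(cm)[fx$sim$mask] ==
              fx$sim$truth$classField[fx$sim$mask])
  expect_gte(acc, 0.9)
  expect_equal(sum(classFractions(cm)), 1)
})

test_that("classification is invariant to affine intensity rescaling", {
  fx <- compactionFixture(seed = 33)
  d1 <- fx$sim$channels$DAPI
  d2 <- VolumeImage(5 * imgData(d1) + 300, voxelSize(d1))
  c1 <- classifyCompaction(d1, fx$mask, K = 7, beta = 0.8)
  c2 <- classifyCompaction(d2, fx$mask, K = 7, beta = 0.8)
  expect_identical(classArray(c1), classArray(c2))
})

test_that("beta = 0 reduces to a plain Gaussian mixture (mclust oracle)", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  fx <- compactionFixture(seed = 34, beta = 0, shape = c(10L, 32L, 32L))
  cm <- classifyCompaction(fx$sim$channels$DAPI, fx$mask, K = 7, beta = 0)
  v <- imgData(fx$sim$channels$DAPI)[fx$sim$mask]
  fit <- mclust::Mclust(v, G = 7, modelNames = "V", verbose = FALSE)
  # align mclust components by ascending mean and compare labelings
  ord <- order(fit$parameters$mean)
  relab <- integer(7); relab[ord] <- 1:7
  oracleLab <- relab[fit$classification]
  agree <- mean(oracleLab == classArray(cm)[fx$sim$mask])
  expect_gte(agree, 0.95)
})

test_that("degenerate inputs are refused", {
  shape <- c(8L, 16L, 16L)
  m <- array(FALSE, shape); m[2:7, 2:15, 2:15] <- TRUE
  nm <- NucleusMask(m, checkConnected = FALSE)
  flat <- VolumeImage(array(7, shape))
  expect_error(classifyCompaction(flat, nm), "constant")
  tiny <- array(FALSE, shape); tiny[4, 4:6, 4:6] <- TRUE
  expect_error(classifyCompaction(VolumeImage(array(rnorm(prod(shape)),
                                                    shape)),
                                  NucleusMask(tiny, checkConnected = FALSE),
                                  K = 7),
               "in-mask voxels")
})

test_that("signal mapping weights classes by intensity and normalizes", {
  fx <- compactionFixture(seed = 35, noiseSd = 0)
  cm <- classifyCompaction(fx$sim$channels$DAPI, fx$mask, K = 7,
                           beta = 0.8)
  cls <- classArray(cm)
  shape <- dim(cls)
  # signal confined to class 3
  sig <- array(0, shape); sig[cls == 3] <- 10
  p <- mapSignalToClasses(VolumeImage(sig), sig > 0, cm)
  expect_equal(p$fractions[3], 1)
  expect_equal(sum(p$fractions), 1)

  # equal total intensity split between classes 2 and 6
  sig2 <- array(0, shape)
  i2 <- which(cls == 2)[seq_len(50)]
  i6 <- which(cls == 6)[seq_len(100)]
  sig2[i2] <- 2; sig2[i6] <- 1
  p2 <- mapSignalToClasses(VolumeImage(sig2), sig2 > 0, cm)
  expect_equal(p2$fractions[c(2, 6)], c(0.5, 0.5))

  # doubling class-6 intensity raises its fraction strictly
  sig3 <- sig2; sig3[i6] <- 2
  p3 <- mapSignalToClasses(VolumeImage(sig3), sig3 > 0, cm)
  expect_gt(p3$fractions[6], p2$fractions[6])

  # zero signal flags instead of dividing by zero
  z <- mapSignalToClasses(VolumeImage(array(0, shape)),
                          array(TRUE, shape), cm)
  expect_true(z$zeroSignal)
  expect_true(all(z$fractions == 0))
})

test_that("early/late signal planted in low/high classes shifts the profile", {
  fx <- compactionFixture(seed = 36, noiseSd = 0)
  cm <- classifyCompaction(fx$sim$channels$DAPI, fx$mask, K = 7,
                           beta = 0.8)
  cls <- classArray(cm)
  shape <- dim(cls)
  early <- array(0, shape); early[cls %in% 1:3] <- 5
  late <- array(0, shape); late[cls %in% 5:7] <- 5
  pe <- mapSignalToClasses(VolumeImage(early), early > 0, cm)$fractions
  pl <- mapSignalToClasses(VolumeImage(late), late > 0, cm)$fractions
  expect_gt(sum(pe[1:3]), 0.99)
  expect_gt(sum(pl[5:7]), 0.99)
})
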