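# Forward model: speckle statistics, linearity, memory correlations.

test_that("point speckle is fully developed, nonnegative and deterministic", {
  cfg <- fixtureConfig()
  scr <- scatteringScreen(cfg, 96, seed = 11, backend = "physical")
  f <- simulatePointSpeckle(c(0, 0), scr)
  I <- intensity(f)
  expect_true(all(is.finite(I)) && all(I >= 0))
  expect_gt(sd(I) / mean(I), 0.8)   # Rayleigh statistics: contrast ~ 1
  expect_lt(sd(I) / mean(I), 1.2)
  # determinism: same seed -> bit-identical
  scr2 <- scatteringScreen(cfg, 96, seed = 11, backend = "physical")
  expect_identical(I, intensity(simulatePointSpeckle(c(0, 0), scr2)))
  # different seed -> different realization
  scr3 <- scatteringScreen(cfg, 96, seed = 12, backend = "physical")
  expect_gt(mean(abs(I - intensity(simulatePointSpeckle(c(0, 0), scr3)))), 0)
  # undersampled configuration refuses to simulate
  expect_error(scatteringScreen(opticalConfig(detectorPitch = 0.05), 96,
                                seed = 1), "undersampled")
})

test_that("shifting a source shifts its speckle by the scaled, reversed lag", {
  cfg <- fixtureConfig()
  scr <- scatteringScreen(cfg, 128, seed = 21, backend = "physical")
  f0 <- simulatePointSpeckle(c(0, 0), scr)
  for (dPx in list(c(8, 0), c(0, -12), c(10, 6))) {
    d <- dPx * cfg@objectPitch
    fi <- simulatePointSpeckle(d, scr)
    xc <- crossCorrelate(fi, f0)
    pk <- which(values(xc) == max(values(xc)), arr.ind = TRUE)
    lag <- c(pk[2] - xc@center[2], pk[1] - xc@center[1]) * cfg@detectorPitch
    # peak at the negated speckle displacement of frame_a relative to
    # frame_b (map convention), i.e. minus objectToDetectorShift(d)
    expect_equal(lag, -objectToDetectorShift(d, cfg),
                 tolerance = 1.01 * cfg@detectorPitch)
    # thin screen: nearby sources stay strongly correlated at the
    # predicted lag
    expect_gt(max(values(xc)), 0.5)
  }
})

test_that("frames are the exact incoherent sum over scene points", {
  cfg <- fixtureConfig()
  p <- cfg@objectPitch
  scr <- scatteringScreen(cfg, 64, seed = 31, backend = "physical")
  pts <- list(c(0, 0), c(6 * p, -4 * p), c(-8 * p, 5 * p))
  w <- c(1.5, 0.7, 1.1)
  scene <- matrix(0, 64, 64)
  for (i in seq_along(pts))
    scene[33 + pts[[i]][2] / p, 33 + pts[[i]][1] / p] <- w[i]
  obj <- methods::new("ObjectScene", intensity = scene, pitch = p,
                      subObjects = list())
  fr <- renderFrame(obj, scr)
  # brute-force oracle: weighted per-point loop
  acc <- matrix(0, 64, 64)
  for (i in seq_along(pts))
    acc <- acc + w[i] * intensity(simulatePointSpeckle(pts[[i]], scr))
  expect_equal(intensity(fr), acc, tolerance = 1e-10)
  # single-point scene identical to the scaled point speckle
  s1 <- matrix(0, 64, 64); s1[33, 33] <- 2.5
  o1 <- methods::new("ObjectScene", intensity = s1, pitch = p,
                     subObjects = list())
  expect_equal(intensity(renderFrame(o1, scr)),
               2.5 * intensity(simulatePointSpeckle(c(0, 0), scr)),
               tolerance = 1e-12)
  # linearity in the scene
  o2 <- methods::new("ObjectScene", intensity = 2 * scene, pitch = p,
                     subObjects = list())
  expect_equal(intensity(renderFrame(o2, scr)), 2 * intensity(fr),
               tolerance = 1e-12)
})

test_that("statistical backend realizes the memory-effect correlations", {
  cfg <- fixtureFiniteMemory(25)
  p <- cfg@objectPitch
  k <- waveNumber(cfg)
  scr <- scatteringScreen(cfg, 128, seed = 7, backend = "statistical")
  seps <- c(0, 5, 10, 15, 20, 25, 30, 40, 50, 60)
  pos <- cbind(seps * p, 0)
  st <- correlatedStack(pos, scr)
  I0 <- intensity(st[[1]])
  dev <- vapply(seq_along(seps), function(i) {
    sh <- round(objectToDetectorShift(pos[i, ] - pos[1, ], cfg) /
                  cfg@detectorPitch)
    realized <- alignedFrameCor(I0, intensity(st[[i]]), sh)
    realized - memoryEnvelope(k * (seps[i] * p / cfg@L_o) * cfg@L)
  }, numeric(1))
  expect_lt(max(abs(dev)), 0.1)          # per-point tolerance
  expect_lt(mean(abs(dev)), 0.05)        # sweep-average much tighter
  # identical positions reproduce the identical frame
  st2 <- correlatedStack(rbind(c(0, 0), c(0, 0)), scr)
  expect_identical(intensity(st2[[1]]), intensity(st2[[2]]))
  # far outside the memory range: uncorrelated
  far <- correlatedStack(rbind(c(0, 0), c(100 * p, 0)), scr)
  sh <- round(objectToDetectorShift(c(100 * p, 0), cfg) / cfg@detectorPitch)
  expect_lt(abs(alignedFrameCor(intensity(far[[1]]), intensity(far[[2]]),
                                sh)), 0.05)
})

test_that("camera noise is unbiased, clipped and deterministic", {
  cfg <- fixtureConfig()
  scr <- scatteringScreen(cfg, 64, seed = 41, backend = "physical")
  f <- simulatePointSpeckle(c(0, 0), scr)
  n1 <- addCameraNoise(f, readSigma = 2, bitDepth = 12, seed = 5,
                       peakCounts = 1500)
  n2 <- addCameraNoise(f, readSigma = 2, bitDepth = 12, seed = 5,
                       peakCounts = 1500)
  expect_identical(intensity(n1), intensity(n2))
  expect_true(all(intensity(n1) >= 0 & intensity(n1) <= 2^12 - 1))
  # unbiased at reasonable counts
  clean <- intensity(f) * (1500 / max(intensity(f)))
  expect_equal(mean(intensity(n1)), mean(clean), tolerance = 0.02)
  # quantization-only when noise is disabled
  q <- addCameraNoise(f, shot = FALSE, readSigma = 0, bitDepth = 16,
                      seed = 1, peakCounts = 30000)
  clean16 <- intensity(f) * (30000 / max(intensity(f)))
  expect_lte(max(abs(intensity(q) - clean16)), 1)
  expect_error(addCameraNoise(f, bitDepth = 10, seed = 1), "bitDepth")
})

test_that("sequence rendering keeps the static background bit-static", {
  cfg <- fixtureFiniteMemory(25)
  p <- cfg@objectPitch
  sq <- makeDotfieldScene(4, dim = c(64, 64), pitch = p, seed = 9,
                          nFrames = 3, region = c(-1.5, 1.5, -1.5, 1.5),
                          minSepPx = 10)
  sq <- applyMotion(sq, 1, linearMotion(3, c(3 * p, 0)))
  scr <- scatteringScreen(cfg, 64, seed = 19, backend = "statistical")
  fr <- renderSequence(sq, scr)
  # a purely static version of the same scene renders identical frames
  sqs <- makeDotfieldScene(4, dim = c(64, 64), pitch = p, seed = 9,
                           nFrames = 3, region = c(-1.5, 1.5, -1.5, 1.5),
                           minSepPx = 10)
  frs <- renderSequence(sqs, scr)
  expect_identical(intensity(frs[[1]]), intensity(frs[[3]]))
  # moving sequences differ between frames
  expect_gt(mean(abs(intensity(fr[[1]]) - intensity(fr[[3]]))), 0)
})
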