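# Lobe extraction, displacement estimation, reference-lag choice and
# trajectory building.

# Differential-style map with one synthetic Gaussian lobe pair on a noise
# floor: + at posPx, - at negPx (px relative to the centre), amplitudes in
# noise-sigma units.  The noise floor carries the sqrt(overlap) variance
# profile of a real zero-padded correlation map.
syntheticDiffMap <- function(n = 64, posPx, negPx, amp = 10, width = 2,
                             seed = 1) {
  set.seed(seed)
  nl <- 2L * n - 1L
  ctr <- c(n, n)
  ovl <- outer(pmax(n - abs(seq_len(nl) - ctr[1]), 1) / n,
               pmax(n - abs(seq_len(nl) - ctr[2]), 1) / n)
  noise <- matrix(rnorm(nl * nl, sd = 1), nl, nl) * sqrt(ovl)
  g <- function(at) {
    x <- outer(rep(1, nl), seq_len(nl) - ctr[2] - at[1])
    y <- outer(seq_len(nl) - ctr[1] - at[2], rep(1, nl))
    exp(-(x^2 + y^2) / (2 * width^2))
  }
  vals <- noise + amp * g(posPx) - amp * g(negPx)
  methods::new("CorrelationMap", values = vals, pitch = 1,
               kind = "differential", normalization = "raw",
               window = "none", center = as.integer(ctr), meta = list())
}

test_that("constructed lobe pairs are found with the right displacement", {
  m <- syntheticDiffMap(64, posPx = c(10, 0), negPx = c(-10, 0), amp = 10)
  ft <- extractMotionFeatures(m, thresholdSigma = 5, excludeRadiusPx = 4)
  expect_length(ft, 1)
  expect_equal(ft[[1]]@displacementDet, c(-20, 0), tolerance = 0.5)
  expect_gt(ft[[1]]@posAmp, 0)
  expect_lt(ft[[1]]@negAmp, 0)
  expect_gt(ft[[1]]@snr, 5)
  # sub-pixel positions: a half-pixel shifted pair is recovered to 0.25 px
  m2 <- syntheticDiffMap(64, posPx = c(8.5, -3.5), negPx = c(-6.5, 2.5),
                         amp = 40, seed = 2)
  f2 <- extractMotionFeatures(m2, thresholdSigma = 5, excludeRadiusPx = 4)
  expect_equal(f2[[1]]@displacementDet, c(-15, 6), tolerance = 0.25)
  expect_true(f2[[1]]@refined)
  # pure-noise map yields nothing at 5 sigma
  mn <- syntheticDiffMap(64, posPx = c(10, 0), negPx = c(-10, 0), amp = 0,
                         seed = 3)
  expect_length(extractMotionFeatures(mn, thresholdSigma = 5,
                                      excludeRadiusPx = 4), 0)
  # wrong map kind is rejected
  ac <- autocorrelate(testImage(16, 1))
  expect_error(extractMotionFeatures(ac), "differential")
})

test_that("feature displacement maps back to the object plane", {
  cfg <- fixtureConfig()
  f <- methods::new("MotionFeature", posLobe = c(0.125, 0),
                    negLobe = c(-0.125, 0), posAmp = 1, negAmp = -1,
                    displacementDet = c(-0.25, 0), snr = 10, refined = TRUE)
  # 0.25 mm detector lobe separation -> 2.15 mm object motion (430/50),
  # sign restored by the axis un-flip
  expect_equal(estimateDisplacement(f, cfg), c(2.15, 0), tolerance = 1e-12)
  f0 <- methods::new("MotionFeature", posLobe = c(0.3, -0.2),
                     negLobe = c(0.3, -0.2), posAmp = 1, negAmp = -1,
                     displacementDet = c(0, 0), snr = 10, refined = TRUE)
  expect_identical(estimateDisplacement(f0, cfg), c(0, 0))
})

test_that("two movers give two features matching both ground truths", {
  cfg <- fixtureConfig()   # thin screen: cleanest lobes
  p <- cfg@objectPitch
  scn <- sceneSequence(list(
    subObject(diskSprite(1.5), c(-18 * p, -10 * p), mobile = TRUE),
    subObject(diskSprite(1.5), c(16 * p, 12 * p), mobile = TRUE),
    subObject(diskSprite(1.5), c(0, 0))), dim = c(128, 128), pitch = p,
    nFrames = 2)
  scn <- applyMotion(scn, 1, data.frame(dx = c(0, 8 * p), dy = c(0, 0)))
  scn <- applyMotion(scn, 2, data.frame(dx = c(0, 0), dy = c(0, -9 * p)))
  scr <- scatteringScreen(cfg, 128, seed = 77, backend = "physical")
  fr <- renderSequence(scn, scr)
  dm <- differentialCorrelation(fr[[2]], fr[[1]])
  ft <- extractMotionFeatures(dm, thresholdSigma = 5, config = cfg,
                              excludeRadiusPx = 6, maxPairDistPx = 15)
  expect_gte(length(ft), 2)
  d <- lapply(ft[1:2], function(f) estimateDisplacement(f, cfg) / p)
  truths <- list(c(8, 0), c(0, -9))
  matched <- sapply(truths, function(tr)
    any(sapply(d, function(x) sqrt(sum((x - tr)^2)) < 1)))
  expect_true(all(matched))
})

test_that("displacement recovery stays subpixel over random motions", {
  cfg <- fixtureFiniteMemory(25)
  p <- cfg@objectPitch
  errs <- vapply(1:20, function(s) {
    ang <- 2 * pi * s / 20
    mag <- 6 + (s %% 5) * 3
    d <- round(c(cos(ang), sin(ang)) * mag)
    scn <- makeDotfieldScene(5, dotRadius = 1.5, starSize = 9,
                             dim = c(128, 128), pitch = p, seed = 100 + s,
                             nFrames = 2, region = c(-30, 30, -30, 30) * p,
                             minSepPx = 16)
    scn <- applyMotion(scn, 1, data.frame(dx = c(0, d[1] * p),
                                          dy = c(0, d[2] * p)))
    scr <- scatteringScreen(cfg, 128, seed = 200 + s,
                            backend = "statistical")
    fr <- renderSequence(scn, scr)
    tab <- trajectoryTable(buildTrajectory(fr, cfg, candidateLags = 1,
                                           excludeRadiusPx = 6))
    sqrt(sum((c(tab$cum_x_mm, tab$cum_y_mm) - d * p)^2)) / p
  }, numeric(1))
  expect_lt(median(errs), 1)
  expect_lt(unname(quantile(errs, 0.95)), 2)
})

test_that("the reference lag adapts to stop-and-go motion", {
  cfg <- fixtureFiniteMemory(25)
  p <- cfg@objectPitch
  scn <- makeDotfieldScene(6, dotRadius = 1.5, starSize = 9,
                           dim = c(128, 128), pitch = p, seed = 42,
                           nFrames = 4, region = c(-40, 40, -40, 40) * p,
                           minSepPx = 16)
  scn <- applyMotion(scn, 1, data.frame(dx = c(0, 8, 8, 8) * p, dy = 0))
  scr <- scatteringScreen(cfg, 128, seed = 52, backend = "statistical")
  fr <- renderSequence(scn, scr)
  # moved only relative to 3 frames ago -> lag 3 wins
  ch <- chooseReferenceLag(fr, 4, candidateLags = c(1, 3), config = cfg,
                           excludeRadiusPx = 6, maxPairDistPx = 25)
  expect_identical(ch$lag, 3L)
  expect_equal(detectorToObjectShift(ch$displacementDet, cfg) / p,
               c(8, 0), tolerance = 1)
  # static history (frames 2..4 are identical) -> no-motion flag
  ch0 <- chooseReferenceLag(fr, 4, candidateLags = c(1, 2), config = cfg,
                            excludeRadiusPx = 6, maxPairDistPx = 25)
  expect_true(ch0$noMotion)
  # single candidate within a too-short history errors
  expect_error(chooseReferenceLag(fr, 1, candidateLags = 1), "candidate")
  expect_error(chooseReferenceLag(list(), 1), "empty")
})

test_that("static scenes yield all-zero trajectories and no false motion", {
  cfg <- fixtureFiniteMemory(25)
  p <- cfg@objectPitch
  nFalse <- 0L
  for (s in 1:8) {
    scn <- makeDotfieldScene(8, dotRadius = 1.5, starSize = 9,
                             dim = c(96, 96), pitch = p, seed = 60 + s,
                             nFrames = 1, region = c(-28, 28, -28, 28) * p,
                             minSepPx = 14)
    scr <- scatteringScreen(cfg, 96, seed = 70 + s, backend = "statistical")
    f1 <- renderFrame(scn@frames[[1]], scr)
    n1 <- addCameraNoise(f1, readSigma = 3, seed = 80 + s,
                         peakCounts = 2000)
    n2 <- addCameraNoise(f1, readSigma = 3, seed = 90 + s,
                         peakCounts = 2000)
    dm <- differentialCorrelation(n2, n1)
    nFalse <- nFalse + length(extractMotionFeatures(dm, thresholdSigma = 5,
                                                    config = cfg))
  }
  expect_identical(nFalse, 0L)
  # a noisy static two-frame sequence tracks to exactly zero
  scn <- makeDotfieldScene(8, dotRadius = 1.5, starSize = 9,
                           dim = c(96, 96), pitch = p, seed = 61,
                           nFrames = 1, region = c(-28, 28, -28, 28) * p,
                           minSepPx = 14)
  scr <- scatteringScreen(cfg, 96, seed = 71, backend = "statistical")
  f1 <- renderFrame(scn@frames[[1]], scr)
  fr <- list(addCameraNoise(f1, readSigma = 3, seed = 1, peakCounts = 2000),
             addCameraNoise(f1, readSigma = 3, seed = 2, peakCounts = 2000),
             addCameraNoise(f1, readSigma = 3, seed = 3, peakCounts = 2000))
  tab <- trajectoryTable(buildTrajectory(fr, cfg, candidateLags = 1))
  expect_identical(max(abs(c(tab$cum_x_mm, tab$cum_y_mm))), 0)
})

test_that("trajectories accumulate exactly and tolerate failing steps", {
  cfg <- fixtureFiniteMemory(25)
  p <- cfg@objectPitch
  scn <- makeDotfieldScene(8, dotRadius = 1.5, starSize = 9,
                           dim = c(128, 128), pitch = p, seed = 23,
                           nFrames = 5, region = c(-35, 35, -35, 35) * p,
                           minSepPx = 16)
  scn <- applyMotion(scn, 1, linearMotion(5, c(6 * p, 3 * p)))
  scr <- scatteringScreen(cfg, 128, seed = 33, backend = "statistical")
  fr <- renderSequence(scn, scr)
  tab <- trajectoryTable(buildTrajectory(fr, cfg, candidateLags = c(1, 2),
                                         excludeRadiusPx = 6))
  expect_identical(nrow(tab), 4L)
  expect_equal(cumsum(tab$dx_mm), tab$cum_x_mm, tolerance = 1e-12)
  expect_equal(cumsum(tab$dy_mm), tab$cum_y_mm, tolerance = 1e-12)
  expect_equal(c(tab$cum_x_mm[4], tab$cum_y_mm[4]) / p, c(24, 12),
               tolerance = 2)
  # a corrupt frame invalidates its step without aborting the track
  fr2 <- fr
  fr2[[3]] <- speckleFrame(matrix(1, 128, 128), pitch = fr[[3]]@pitch)
  tab2 <- trajectoryTable(buildTrajectory(fr2, cfg, candidateLags = 1))
  expect_false(tab2$valid[2])
  expect_true(all(tab2$valid[c(1, 4)]))
})

test_that("rotation about a pivot is recovered from the lobe geometry", {
  cfg <- fixtureConfig()
  p <- cfg@objectPitch
  errs <- vapply(1:3, function(s) {
    pivot <- c(0, 0); radius <- 18 * p; ang0 <- 30 * s; dAng <- 25
    pos0 <- pivot + radius * c(cospi(ang0 / 180), sinpi(ang0 / 180))
    pos1 <- pivot + radius * c(cospi((ang0 + dAng) / 180),
                               sinpi((ang0 + dAng) / 180))
    qref <- c(-24 * p, -18 * p)
    scn <- sceneSequence(list(
      subObject(diskSprite(1.5), pos0, mobile = TRUE),
      subObject(diskSprite(1.5), qref)), dim = c(128, 128), pitch = p,
      nFrames = 2)
    scn <- applyMotion(scn, 1, data.frame(dx = c(0, pos1[1] - pos0[1]),
                                          dy = c(0, pos1[2] - pos0[2])))
    scr <- scatteringScreen(cfg, 128, seed = 400 + s, backend = "physical")
    fr <- renderSequence(scn, scr)
    dm <- differentialCorrelation(fr[[2]], fr[[1]])
    ft <- extractMotionFeatures(dm, thresholdSigma = 5, config = cfg,
                                excludeRadiusPx = 6)
    pivLag <- objectToDetectorShift(pivot - qref, cfg)
    abs(estimateRotationAngle(ft[[1]], pivLag) - dAng)
  }, numeric(1))
  expect_lt(max(errs), 2)
})
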