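# FFT correlations against the direct-summation oracle, and their
# structural invariants.

test_that("auto/cross/differential match the direct-sum oracle on small inputs", {
  for (n in c(8, 13, 16)) {
    a <- testImage(n, seed = n)
    b <- testImage(n, seed = n + 100)
    refA <- xcorrOracleMS(a, a)
    refX <- xcorrOracleMS(a, b)
    tolA <- 1e-9 * max(abs(refA))
    expect_equal(values(autocorrelate(a, normalize = "raw")), refA,
                 tolerance = tolA)
    expect_equal(values(crossCorrelate(a, b, normalize = "raw")), refX,
                 tolerance = tolA)
    expect_equal(values(differentialCorrelation(a, b, normalize = "raw")),
                 refX - refA, tolerance = tolA)
  }
})

test_that("two equal points give half-height side peaks at their separation", {
  img <- matrix(0, 8, 8)
  img[3, 2] <- 1; img[3, 6] <- 1          # separation (4, 0) in (x, y)
  m <- autocorrelate(img, normalize = "raw")
  ref <- xcorrOracleMS(img, img)
  expect_equal(values(m), ref, tolerance = 1e-12)
  ctr <- m@center
  expect_equal(values(m)[ctr[1], ctr[2]], max(values(m)))
  side <- values(m)[ctr[1], ctr[2] + 4]
  # mean-subtracted linear correlation: side peak at half the central one
  expect_equal(side / values(m)[ctr[1], ctr[2]], 0.5, tolerance = 1e-10)
  expect_equal(values(m)[ctr[1], ctr[2] - 4], side, tolerance = 1e-12)
})

test_that("autocorrelations are centrosymmetric with their max at zero lag", {
  for (seed in 1:3) {
    img <- testImage(32, seed)
    m <- values(autocorrelate(img))
    rot <- m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
    expect_lt(max(abs(m - rot)), 1e-9 * max(abs(m)))
    ctr <- which(m == max(m), arr.ind = TRUE)
    expect_equal(as.integer(ctr[1, ]), c(32L, 32L))   # zero lag at (n, n)
  }
})

test_that("cross-correlation identities hold", {
  a <- testImage(16, 4)
  # cross(f, f) == auto(f), exactly
  expect_identical(values(crossCorrelate(a, a)), values(autocorrelate(a)))
  # integer shift recovered exactly: b(x) = a(x - s) -> peak at -s
  s <- c(3, -2)                            # (x, y)
  b <- a[(seq_len(16) - 1 - s[2]) %% 16 + 1,
         (seq_len(16) - 1 - s[1]) %% 16 + 1]    # b(x) = a(x - s), circular
  xc <- crossCorrelate(b, a, normalize = "coeff")
  pk <- which(values(xc) == max(values(xc)), arr.ind = TRUE)
  expect_equal(c(pk[2] - xc@center[2], pk[1] - xc@center[1]), -s)
  # bilinearity in the mean-subtracted inputs
  c1 <- testImage(16, 5); c2 <- testImage(16, 6)
  lhs <- values(crossCorrelate(a, 2 * (c1 - mean(c1)) + 3 * (c2 - mean(c2)),
                               normalize = "raw"))
  rhs <- 2 * values(crossCorrelate(a, c1 - mean(c1), normalize = "raw")) +
    3 * values(crossCorrelate(a, c2 - mean(c2), normalize = "raw"))
  expect_equal(lhs, rhs, tolerance = 1e-10 * max(abs(lhs)))
  # degenerate input rejected
  expect_error(autocorrelate(matrix(1, 8, 8)), "degenerate")
  expect_error(crossCorrelate(a, testImage(8, 1)), "shape")
})

test_that("differential of identical frames is exactly the zero map", {
  a <- testImage(24, 9)
  for (win in c("none", "tukey")) {
    d <- differentialCorrelation(a, a, window = win)
    expect_identical(unique(as.numeric(values(d))), 0)
    expect_identical(d@kind, "differential")
  }
})

test_that("every correlation map sums to zero (mean-subtracted inputs)", {
  a <- testImage(20, 2); b <- testImage(20, 3)
  for (win in c("none", "tukey")) {
    expect_lt(abs(sum(values(autocorrelate(a, window = win)))), 1e-10)
    expect_lt(abs(sum(values(crossCorrelate(a, b, window = win)))), 1e-10)
  }
})

test_that("independent speckle frames decorrelate", {
  cfg <- fixtureConfig()
  s1 <- scatteringScreen(cfg, 64, seed = 1, backend = "physical")
  s2 <- scatteringScreen(cfg, 64, seed = 2, backend = "physical")
  f1 <- simulatePointSpeckle(c(0, 0), s1)
  f2 <- simulatePointSpeckle(c(0, 0), s2)
  xc <- crossCorrelate(f1, f2)
  noise <- mapNoiseLevel(xc)
  expect_lt(max(abs(values(xc))), 5 * noise * sqrt(64))  # no shared structure
  expect_lt(max(abs(values(xc))), 0.5 * max(values(autocorrelate(f1))))
})

test_that("predicted autocorrelation reproduces simple analytic cases", {
  cfg <- fixtureConfig()
  p <- cfg@objectPitch
  krn <- memoryKernel(cfg)
  # point object: the map is the kernel's on-diagonal Gaussian profile
  s1 <- matrix(0, 32, 32); s1[17, 17] <- 1
  o1 <- methods::new("ObjectScene", intensity = s1, pitch = p,
                     subObjects = list())
  m1 <- predictedAutocorrelation(o1, krn, 32)
  v1 <- values(m1)
  ctr <- m1@center
  expect_equal(which(v1 == max(v1), arr.ind = TRUE)[1, ],
               c(row = ctr[1], col = ctr[2]))
  k <- waveNumber(cfg)
  sig <- cfg@L_s / (k * cfg@sigma)
  lag <- 5 * cfg@detectorPitch
  expect_equal(v1[ctr[1], ctr[2] + 5] / v1[ctr[1], ctr[2]],
               exp(-(lag / sig)^2), tolerance = 1e-9)
  # two-point object: three kernel-blurred peaks with 2:1 weights
  s2 <- matrix(0, 32, 32); s2[17, 13] <- 1; s2[17, 21] <- 1
  o2 <- methods::new("ObjectScene", intensity = s2, pitch = p,
                     subObjects = list())
  v2 <- values(predictedAutocorrelation(o2, krn, 32))
  sep <- 8L  # object px -> detector px with the default matched pitches
  expect_equal(v2[ctr[1], ctr[2]] / v2[ctr[1], ctr[2] + sep], 2,
               tolerance = 0.01)
  expect_equal(v2[ctr[1], ctr[2] - sep], v2[ctr[1], ctr[2] + sep],
               tolerance = 1e-9)
})

test_that("ensemble autocorrelation converges to the model prediction", {
  cfg <- fixtureConfig()
  p <- cfg@objectPitch
  s <- matrix(0, 96, 96)
  s[49, 49] <- 1; s[52, 61] <- 1; s[40, 42] <- 1
  obj <- methods::new("ObjectScene", intensity = s, pitch = p,
                      subObjects = list())
  fr <- lapply(1:12, function(i)
    renderFrame(obj, scatteringScreen(cfg, 96, seed = 500 + i,
                                      backend = "physical")))
  em <- ensembleAutocorrelation(fr, normalize = "raw")
  # N = 1 equals the plain autocorrelation
  expect_equal(values(ensembleAutocorrelation(fr[1], normalize = "raw")),
               values(autocorrelate(fr[[1]], normalize = "raw")),
               tolerance = 1e-12)
  pred <- predictedAutocorrelation(obj, memoryKernel(cfg), 96)
  expect_gt(mapCor(em, pred), 0.9)
  # averaging suppresses off-peak fluctuations roughly like 1/sqrt(N)
  off <- function(m) {
    v <- values(m); ctr <- m@center
    v[ctr[1], ] <- NA; v[, ctr[2]] <- NA
    resid <- v - values(pred) * sum(v * values(pred), na.rm = TRUE) /
      sum(values(pred)^2)
    sd(resid, na.rm = TRUE)
  }
  r6 <- off(ensembleAutocorrelation(fr[1:6], normalize = "raw"))
  r12 <- off(em)
  expect_equal(r6 / r12, sqrt(2), tolerance = 0.25 * sqrt(2))
})
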