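# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# Reference experiment geometry (He-Ne, 430 mm / 50 mm) with defaults.
fixtureConfig <- function(...) opticalConfig(...)

# Geometry with a finite memory range of `rangePx` object-plane pixels.
fixtureFiniteMemory <- function(rangePx = 25) {
  cfg <- opticalConfig()
  opticalConfig(L = thicknessForMemoryRange(cfg, rangePx * cfg@objectPitch))
}

# Independent evaluation of the memory envelope, written with expm1/exp
# instead of sinh so it does not share the implementation's code path.
envelopeOracle <- function(x) {
  x <- abs(x)
  ifelse(x == 0, 1, (2 * x / (exp(x) - exp(-x)))^2)
}

# Direct O(N^4) summation oracle for the full linear cross-correlation of
# two equal-size matrices: X[l] = sum_x a(x) b(x + l), lags -(n-1)..(n-1),
# zero lag at index (n, n).
xcorrOracle <- function(a, b) {
  n <- dim(a)
  out <- matrix(0, 2 * n[1] - 1, 2 * n[2] - 1)
  for (lr in -(n[1] - 1):(n[1] - 1)) {
    for (lc in -(n[2] - 1):(n[2] - 1)) {
      s <- 0
      for (r in seq_len(n[1])) {
        r2 <- r + lr
        if (r2 < 1 || r2 > n[1]) next
        for (c in seq_len(n[2])) {
          c2 <- c + lc
          if (c2 < 1 || c2 > n[2]) next
          s <- s + a[r, c] * b[r2, c2]
        }
      }
      out[lr + n[1], lc + n[2]] <- s
    }
  }
  out
}

# Mean-subtracted oracle matching the package's "raw" normalization.
xcorrOracleMS <- function(a, b) xcorrOracle(a - mean(a), b - mean(b))

# Small deterministic pseudo-speckle matrix (not a physical simulation;
# just a reproducible non-constant test image).
testImage <- function(n, seed = 1) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

# Pearson correlation between two correlation maps' values.
mapCor <- function(a, b) cor(as.numeric(values(a)), as.numeric(values(b)))

# Realized intensity correlation between two frames after aligning the
# second by the detector-mapped shift of its source separation.
alignedFrameCor <- function(I0, Ii, shiftPx) {
  n <- dim(I0)
  r0 <- max(1, 1 - shiftPx[2]):min(n[1], n[1] - shiftPx[2])
  c0 <- max(1, 1 - shiftPx[1]):min(n[2], n[2] - shiftPx[1])
  cor(as.numeric(I0[r0, c0]),
      as.numeric(Ii[r0 + shiftPx[2], c0 + shiftPx[1]]))
}
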