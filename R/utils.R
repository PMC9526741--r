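# Internal helpers: seeding, FFT index gymnastics, windows, subpixel fits.

# Derive a reproducible sub-stream seed (< 2^31) from a top-level seed and a
# stream label, so screen / noise / scene randomness can be re-seeded
# independently of each other.
.deriveSeed <- function(seed, label) {
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v) * 2654435.0) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h + 1) %% 2147483647)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Swap quadrants so the zero-frequency / zero-lag sample moves to the centre
# (n/2 + 1 for even n).  .ifftshift2 undoes it for odd sizes as well.
.fftshift2 <- function(m) {
  d <- dim(m)
  i <- c(seq.int(floor(d[1] / 2) + 1L, d[1]), seq_len(floor(d[1] / 2)))
  j <- c(seq.int(floor(d[2] / 2) + 1L, d[2]), seq_len(floor(d[2] / 2)))
  m[i, j, drop = FALSE]
}

.ifftshift2 <- function(m) {
  d <- dim(m)
  i <- c(seq.int(ceiling(d[1] / 2) + 1L, d[1]), seq_len(ceiling(d[1] / 2)))
  j <- c(seq.int(ceiling(d[2] / 2) + 1L, d[2]), seq_len(ceiling(d[2] / 2)))
  m[i, j, drop = FALSE]
}

# Centered coordinate axis for an n-sample grid with pitch p: the origin sits
# at index floor(n/2) + 1, matching the FFT centre convention used throughout.
.axis0 <- function(n, pitch = 1) {
  (seq_len(n) - (floor(n / 2) + 1L)) * pitch
}

# 1-D Tukey (tapered-cosine) window, alpha = taper fraction.
.tukey <- function(n, alpha = 0.25) {
  if (alpha <= 0) return(rep(1, n))
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / alpha - 2 / alpha + 1)))
  w
}

.tukey2 <- function(dim, alpha = 0.25) {
  outer(.tukey(dim[1], alpha), .tukey(dim[2], alpha))
}

# Three-point parabolic interpolation of an extremum position.
# Returns the fractional offset in (-0.5, 0.5); NA if the fit degenerates.
.parabolicOffset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * 100) return(NA_real_)
  off <- 0.5 * (ym1 - yp1) / denom
  if (!is.finite(off) || abs(off) > 1) NA_real_ else off
}

# Full linear (zero-padded) cross-correlation of two equal-size real
# matrices: X[l] = sum_x a(x) * b(x + l), lags -(n-1)..(n-1) on each axis,
# zero lag at index (n, n) of the (2n-1)-sized output.
.xcorrCore <- function(a, b) {
  n <- dim(a)
  P <- 2L * n
  A <- matrix(0, P[1], P[2]); A[seq_len(n[1]), seq_len(n[2])] <- a
  B <- matrix(0, P[1], P[2]); B[seq_len(n[1]), seq_len(n[2])] <- b
  cc <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE)) /
    prod(P)
  i <- c(seq.int(P[1] - n[1] + 2L, P[1]), seq_len(n[1]))
  j <- c(seq.int(P[2] - n[2] + 2L, P[2]), seq_len(n[2]))
  cc[i, j, drop = FALSE]
}

.assertMatrix <- function(x, what = "input") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

.vlen <- function(v) sqrt(sum(v^2))
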