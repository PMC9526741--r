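# Scattering-screen realizations: thin random phase screen (physical
# backend) and spectral correlated-field synthesis (statistical backend).

#' Construct a scattering screen
#'
#' Fixes the random realization of the scattering layer for a whole
#' simulated sequence (the layer is static in the experiment).  Two
#' backends:
#' \describe{
#'   \item{physical}{A single thin random phase screen illuminated by a
#'     spherical wave from each source point and propagated to the detector
#'     with a band-limited angular-spectrum transfer function.  A thin
#'     screen has an essentially unlimited memory range over the simulated
#'     field of view, so this backend serves as the exact-physics oracle.}
#'   \item{statistical}{Correlated-field synthesis that imposes the
#'     finite memory-effect envelope directly: the screen field seen from
#'     source angle \eqn{\theta} is a fixed weighted sum of independent
#'     white complex Gaussian fields with phase factors
#'     \eqn{e^{i q\cdot k L \theta}}, the weights sampling the 2-D spectral
#'     density of the target field correlation
#'     \eqn{\rho(\Delta) = x/\sinh x} (the square root of the intensity
#'     envelope, per the Siegert relation for circular Gaussian fields).
#'     Any two source positions then realize the memory-effect intensity
#'     correlation, and a fixed position always reproduces the identical
#'     speckle, so static objects stay exactly static.}
#' }
#'
#' @param config An [OpticalConfig-class].
#' @param frameDim Detector frame size (rows, cols) in pixels; scalars are
#'   recycled to square frames.  The simulation grid is padded to twice this
#'   size so speckle shifts up to half a frame do not wrap.
#' @param seed Integer seed; screens are deterministic given the seed.
#' @param backend "physical" or "statistical".
#' @param thetaExtent Statistical backend only: maximum object-plane source
#'   separation (mm, length 1 or 2 for x/y) the spectral grid must resolve.
#'   Defaults to the detector field of view mapped to the object plane.
#' @param massCutoff Statistical backend: fraction of the spectral mass to
#'   retain when truncating the frequency grid.
#' @param maxComponents Statistical backend: hard cap on the number of
#'   spectral components (highest-weight components are kept).
#' @return A [PhysicalScreen-class] or [SpectralScreen-class].
#' @examples
#' scr <- scatteringScreen(opticalConfig(), 64, seed = 1)
#' @export
scatteringScreen <- function(config, frameDim, seed,
                             backend = c("physical", "statistical"),
                             thetaExtent = NULL, massCutoff = 0.999,
                             maxComponents = 600L) {
  backend <- match.arg(backend)
  frameDim <- as.integer(rep(frameDim, length.out = 2))
  if (any(frameDim < 8L)) stop("frameDim must be at least 8", call. = FALSE)
  expectedGrainDiameter(config)   # undersampling guard
  P <- 2L * frameDim
  if (backend == "physical") {
    phase <- .withSeed(.deriveSeed(seed, "screen-phase"),
                       matrix(stats::runif(prod(P), 0, 2 * pi), P[1], P[2]))
    methods::new("PhysicalScreen", seed = as.integer(seed),
                 frameDim = frameDim, config = config, phase = phase)
  } else {
    .spectralScreen(config, frameDim, seed, thetaExtent, massCutoff,
                    maxComponents)
  }
}

# Radial 2-D spectral density of rho(r) = r / sinh(r) at radial
# frequencies q (Hankel transform of order 0); rho is completely monotone
# in r^2, hence positive definite in 2-D, so S >= 0 up to quadrature error.
.rhoSpectrumRadial <- function(q) {
  r <- seq(1e-4, 30, length.out = 3000)
  dr <- r[2] - r[1]
  rho <- r / sinh(r)
  vapply(q, function(qi) sum(rho * besselJ(qi * r, 0) * r) * dr, numeric(1))
}

.spectralScreen <- function(config, frameDim, seed, thetaExtent, massCutoff,
                            maxComponents) {
  P <- 2L * frameDim
  k <- waveNumber(config)
  if (is.null(thetaExtent))
    thetaExtent <- frameDim * config@detectorPitch * config@L_o / config@L_s
  thetaExtent <- rep(as.numeric(thetaExtent), length.out = 2)
  # screen sampling pitch implied by the Fourier far-field mapping
  ps <- config@wavelength * config@L_s / (P[1] * config@detectorPitch)
  if (4 * config@sigma > 0.95 * P[1] * ps)
    stop("illumination aperture exceeds the simulation grid; reduce sigma ",
         "or the detector pitch", call. = FALSE)
  # maximum source separation in scaled angle units t = k * L * theta
  tmax <- k * config@L * thetaExtent / config@L_o
  if (max(tmax) < 0.05) {
    # effectively unlimited memory range over the extent: one fully
    # correlated component
    qx <- 0; qy <- 0; w <- 1
  } else {
    dq <- 2 * pi / pmax(2.5 * tmax, 6)
    # radial mass profile to pick the truncation frequency
    qr <- seq(0, 12, length.out = 241)
    Sr <- .rhoSpectrumRadial(qr)
    Sr[Sr < 0] <- 0
    mass <- cumsum(Sr * qr)            # 2-D isotropic mass ~ S(q) q dq
    mass <- mass / mass[length(mass)]
    qhi <- qr[which(mass >= massCutoff)[1]]
    K <- pmax(ceiling(qhi / dq), 0L)
    gx <- dq[1] * seq.int(-K[1], K[1])
    gy <- dq[2] * seq.int(-K[2], K[2])
    qx <- rep(gx, times = length(gy))
    qy <- rep(gy, each = length(gx))
    w <- .rhoSpectrumRadial(sqrt(qx^2 + qy^2))
    neg <- sum(pmin(w, 0))
    if (abs(neg) > 0.01 * sum(abs(w)))
      warning("target correlation structure not exactly realizable; ",
              "falling back to the nearest feasible (clipped) spectrum")
    w[w < 0] <- 0
    keep <- w > 1e-6 * max(w)
    qx <- qx[keep]; qy <- qy[keep]; w <- w[keep]
    if (length(w) > maxComponents) {
      ord <- order(w, decreasing = TRUE)[seq_len(maxComponents)]
      qx <- qx[ord]; qy <- qy[ord]; w <- w[ord]
    }
    w <- w / sum(w)
  }
  M <- length(w)
  fields <- .withSeed(.deriveSeed(seed, "spectral-fields"), {
    n <- prod(P) * M
    matrix(complex(real = stats::rnorm(n, sd = sqrt(0.5)),
                   imaginary = stats::rnorm(n, sd = sqrt(0.5))),
           prod(P), M)
  })
  methods::new("SpectralScreen", seed = as.integer(seed),
               frameDim = frameDim, config = config, fields = fields,
               qx = qx, qy = qy, weights = w, screenPitch = ps,
               thetaExtent = thetaExtent)
}

setMethod("show", "PhysicalScreen", function(object) {
  cat(sprintf("PhysicalScreen (thin phase screen), seed %d, for %dx%d frames (grid %dx%d)\n",
              object@seed, object@frameDim[1], object@frameDim[2],
              2L * object@frameDim[1], 2L * object@frameDim[2]))
})

setMethod("show", "SpectralScreen", function(object) {
  cat(sprintf(paste0("SpectralScreen (correlated-field synthesis), seed %d, ",
                     "for %dx%d frames\n  %d spectral component(s), theta ",
                     "extent %.3g x %.3g mm (object plane)\n"),
              object@seed, object@frameDim[1], object@frameDim[2],
              length(object@weights), object@thetaExtent[1],
              object@thetaExtent[2]))
})
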