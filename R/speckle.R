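# Forward model: detector-plane speckle frames from hidden scenes.
#
# The measured intensity is the incoherent sum over object points,
# I(x_d) = sum_i O(x_i) S(x_i, x_d): per-point speckles add in intensity,
# never in field, so the forward model is exactly linear in the scene.

#' Speckle frame constructor
#'
#' @param intensity Nonnegative numeric matrix.
#' @param pitch Detector pitch (mm/px).
#' @param exposure Exposure metadata (s).
#' @param meta Metadata list.
#' @return A [SpeckleFrame-class].
#' @export
speckleFrame <- function(intensity, pitch, exposure = 3, meta = list()) {
  methods::new("SpeckleFrame", intensity = intensity, pitch = pitch,
               exposure = exposure, meta = meta)
}

# ---- per-backend point-source speckle ----------------------------------

# Gaussian illumination amplitude on the layer: intensity profile
# exp(-|xi|^2 / (2 sigma^2)) (beam intensity variance sigma^2), i.e.
# amplitude exp(-|xi|^2 / (4 sigma^2)).  With this profile the realized
# speckle correlation versus lag mismatch reproduces the kernel's Gaussian
# factor exactly (the field correlation is the Fourier transform of the
# intensity profile on the layer).
.apertureAmplitude <- function(X2, sigma) exp(-X2 / (4 * sigma^2))

# Sum of weighted point-source speckles for a physical screen.
# positions: n x 2 matrix (x, y) mm on the object plane.
.renderPointsPhysical <- function(positions, weights, screen) {
  cfg <- screen@config
  N <- screen@frameDim
  P <- 2L * N
  pd <- cfg@detectorPitch
  k <- waveNumber(cfg)
  xs <- .axis0(P[2], pd)
  ys <- .axis0(P[1], pd)
  X <- outer(rep(1, P[1]), xs)
  Y <- outer(ys, rep(1, P[2]))
  A <- .apertureAmplitude(X^2 + Y^2, cfg@sigma)
  normA <- sum(A^2)
  # source-independent part: aperture, random phase, common spherical term
  base <- A * exp(1i * (screen@phase + k * (X^2 + Y^2) / (2 * cfg@L_o)))
  # band-limited angular-spectrum transfer function for distance L_s
  fx <- c(seq.int(0L, P[2] / 2L - 1L), seq.int(-P[2] / 2L, -1L)) / (P[2] * pd)
  fy <- c(seq.int(0L, P[1] / 2L - 1L), seq.int(-P[1] / 2L, -1L)) / (P[1] * pd)
  FX <- outer(rep(1, P[1]), fx)
  FY <- outer(fy, rep(1, P[2]))
  arg <- 1 / cfg@wavelength^2 - FX^2 - FY^2
  flx <- 1 / (cfg@wavelength * sqrt((2 * fx[2] * cfg@L_s)^2 + 1))
  fly <- 1 / (cfg@wavelength * sqrt((2 * fy[2] * cfg@L_s)^2 + 1))
  mask <- (arg > 0) & (abs(FX) < flx) & (abs(FY) < fly)
  H <- matrix(0i, P[1], P[2])
  H[mask] <- exp(2i * pi * cfg@L_s * sqrt(arg[mask]))
  rows <- seq.int(N[1] / 2L + 1L, N[1] / 2L + N[1])
  cols <- seq.int(N[2] / 2L + 1L, N[2] / 2L + N[2])
  out <- matrix(0, N[1], N[2])
  for (i in seq_len(nrow(positions))) {
    ramp <- exp(-1i * k * (X * positions[i, 1] + Y * positions[i, 2]) /
                  cfg@L_o)
    u <- stats::fft(stats::fft(base * ramp) * H, inverse = TRUE) / prod(P)
    out <- out + weights[i] * (Mod(u[rows, cols])^2 / normA)
  }
  out
}

# Sum of weighted point-source speckles for a spectral screen.
.renderPointsSpectral <- function(positions, weights, screen,
                                  chunk = 32L) {
  cfg <- screen@config
  N <- screen@frameDim
  P <- 2L * N
  ps <- screen@screenPitch
  k <- waveNumber(cfg)
  xs <- .axis0(P[2], ps)
  ys <- .axis0(P[1], ps)
  X <- outer(rep(1, P[1]), xs)
  Y <- outer(ys, rep(1, P[2]))
  A <- .apertureAmplitude(X^2 + Y^2, cfg@sigma)
  normA <- sum(A^2)
  n <- nrow(positions)
  theta <- positions / cfg@L_o
  ext <- screen@thetaExtent
  sepx <- diff(range(positions[, 1])); sepy <- diff(range(positions[, 2]))
  if (sepx > ext[1] + 1e-9 || sepy > ext[2] + 1e-9)
    warning("source separations exceed the screen's thetaExtent; ",
            "realized correlations may wrap")
  t1 <- k * cfg@L * theta[, 1]
  t2 <- k * cfg@L * theta[, 2]
  coefs <- sqrt(screen@weights) *
    exp(1i * (outer(screen@qx, t1) + outer(screen@qy, t2)))   # M x n
  rows <- seq.int(N[1] / 2L + 1L, N[1] / 2L + N[1])
  cols <- seq.int(N[2] / 2L + 1L, N[2] / 2L + N[2])
  out <- matrix(0, N[1], N[2])
  for (st in seq.int(1L, n, by = chunk)) {
    en <- min(st + chunk - 1L, n)
    E <- screen@fields %*% coefs[, st:en, drop = FALSE]   # P^2 x chunk
    for (j in seq.int(st, en)) {
      e <- matrix(E[, j - st + 1L], P[1], P[2])
      ramp <- exp(-1i * k * (X * theta[j, 1] + Y * theta[j, 2]))
      v <- .fftshift2(stats::fft(e * A * ramp))
      out <- out + weights[j] * (Mod(v[rows, cols])^2 / normA)
    }
  }
  out
}

.renderPoints <- function(positions, weights, screen) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  if (nrow(positions) < 1) stop("at least one source position is required",
                                call. = FALSE)
  if (any(!is.finite(positions))) stop("non-finite source position",
                                       call. = FALSE)
  out <- if (methods::is(screen, "PhysicalScreen"))
    .renderPointsPhysical(positions, weights, screen)
  else
    .renderPointsSpectral(positions, weights, screen)
  if (any(!is.finite(out)))
    stop("forward model produced non-finite intensities", call. = FALSE)
  out
}

# ---- exported operations -----------------------------------------------

#' Speckle pattern of a single hidden point source
#'
#' Physical backend: a spherical wave from the source illuminates the
#' random phase screen through the Gaussian beam profile and is propagated
#' to the detector by a band-limited angular-spectrum kernel; the frame is
#' \eqn{|field|^2}, fully developed speckle with unit contrast.  Statistical
#' backend: the source's correlated screen field (see
#' [SpectralScreen-class]) is Fourier-propagated.  Either way a source
#' shifted by d on the object plane shifts its speckle by
#' \code{objectToDetectorShift(d)} while decorrelating according to the
#' memory envelope (statistical backend) or negligibly (thin physical
#' screen).
#'
#' @param x_o Object-plane position (x, y) in mm.
#' @param screen A [ScatteringScreen-class].
#' @return A [SpeckleFrame-class].
#' @export
simulatePointSpeckle <- function(x_o, screen) {
  speckleFrame(.renderPoints(matrix(x_o, 1), 1, screen),
               pitch = screen@config@detectorPitch,
               meta = list(backend = class(screen), seed = screen@seed,
                           source = x_o))
}

#' Render a speckle frame from a hidden scene
#'
#' Discretizes the incoherent-sum forward model as a weighted sum over the
#' scene's lit object pixels: per-point speckles are added in intensity
#' with no interference cross-terms, so the result is exactly linear in the
#' scene.
#'
#' @param scene An [ObjectScene-class].
#' @param screen A [ScatteringScreen-class] (its class selects the
#'   backend).
#' @param maxSources Safety cap on the number of lit object pixels.
#' @return A [SpeckleFrame-class].
#' @export
renderFrame <- function(scene, screen, maxSources = 20000L) {
  lay <- .renderLayer(scene@intensity, scene@pitch, screen, maxSources)
  speckleFrame(lay, pitch = screen@config@detectorPitch,
               meta = list(backend = class(screen), seed = screen@seed))
}

.renderLayer <- function(intens, pitch, screen, maxSources = 20000L) {
  lit <- which(intens > 0, arr.ind = TRUE)
  if (nrow(lit) == 0) return(matrix(0, screen@frameDim[1], screen@frameDim[2]))
  if (nrow(lit) > maxSources)
    stop("scene has ", nrow(lit), " lit pixels (> maxSources); coarsen the ",
         "object grid", call. = FALSE)
  d <- dim(intens)
  cx <- floor(d[2] / 2) + 1L
  cy <- floor(d[1] / 2) + 1L
  pos <- cbind((lit[, 2] - cx) * pitch, (lit[, 1] - cy) * pitch)
  .renderPoints(pos, intens[lit], screen)
}

#' Render a whole scene sequence
#'
#' The static sub-objects' speckle contribution is rendered once and shared
#' across frames (it is bit-identical frame to frame, as for a truly static
#' background behind a static screen); only the moving layer is re-rendered
#' per frame.
#'
#' @param seq A [SceneSequence-class].
#' @param screen A [ScatteringScreen-class].
#' @param noise Optional list of [addCameraNoise()] arguments (e.g.
#'   \code{list(readSigma = 2, bitDepth = 16, peakCounts = 3000)}) applied
#'   to every frame with per-frame derived seeds.
#' @param seed Seed for the noise streams (required when \code{noise} is
#'   given).
#' @return List of [SpeckleFrame-class].
#' @export
renderSequence <- function(seq, screen, noise = NULL, seed = NULL) {
  f1 <- seq@frames[[1]]
  dims <- dim(f1@intensity)
  statIdx <- which(!vapply(f1@subObjects, function(s) s@mobile, logical(1)))
  staticLayer <- if (length(statIdx))
    Reduce(`+`, lapply(f1@subObjects[statIdx], .rasterSub, dim = dims,
                       pitch = f1@pitch))
  else matrix(0, dims[1], dims[2])
  staticSpeckle <- .renderLayer(staticLayer, f1@pitch, screen)
  out <- vector("list", length(seq@frames))
  for (t in seq_along(seq@frames)) {
    mobileLayer <- pmax(seq@frames[[t]]@intensity - staticLayer, 0)
    I <- staticSpeckle + .renderLayer(mobileLayer, f1@pitch, screen)
    fr <- speckleFrame(I, pitch = screen@config@detectorPitch,
                       meta = list(backend = class(screen),
                                   seed = screen@seed, frame = t))
    if (!is.null(noise)) {
      if (is.null(seed)) stop("'seed' is required when noise is requested",
                              call. = FALSE)
      fr <- do.call(addCameraNoise,
                    c(list(frame = fr,
                           seed = .deriveSeed(seed, paste0("noise-", t))),
                      noise))
    }
    out[[t]] <- fr
  }
  out
}

#' Speckle stack for a list of point-source positions
#'
#' One frame per source position, all on the same screen, so the pairwise
#' frame correlations realize the memory-effect kernel (statistical
#' backend) or near-perfect shifted copies (thin physical screen).
#' Identical positions reproduce the identical frame.
#'
#' @param positions n x 2 matrix (or list) of object-plane positions (mm).
#' @param screen A [ScatteringScreen-class].
#' @return List of [SpeckleFrame-class].
#' @export
correlatedStack <- function(positions, screen) {
  if (is.list(positions)) positions <- do.call(rbind, positions)
  positions <- matrix(as.numeric(positions), ncol = 2)
  lapply(seq_len(nrow(positions)), function(i)
    simulatePointSpeckle(positions[i, ], screen))
}

#' Add camera noise to a frame
#'
#' Poisson shot noise on the photon counts, additive Gaussian read noise,
#' then quantization and clipping to the ADC bit depth.  Deterministic
#' given the seed.
#'
#' @param frame A [SpeckleFrame-class].
#' @param shot Apply Poisson shot noise?
#' @param readSigma Read-noise standard deviation (counts).
#' @param bitDepth ADC bit depth (8, 12 or 16).
#' @param seed Integer seed.
#' @param peakCounts If given, the clean frame is scaled so its maximum
#'   equals this many counts before noise is applied (otherwise the frame
#'   values are taken as counts).
#' @return A [SpeckleFrame-class] with integer count values.
#' @export
addCameraNoise <- function(frame, shot = TRUE, readSigma = 0, bitDepth = 16,
                           seed, peakCounts = NULL) {
  if (!bitDepth %in% c(8, 12, 16))
    stop("'bitDepth' must be 8, 12 or 16", call. = FALSE)
  if (readSigma < 0) stop("'readSigma' must be >= 0", call. = FALSE)
  I <- frame@intensity
  if (!is.null(peakCounts)) {
    mx <- max(I)
    if (mx > 0) I <- I * (peakCounts / mx)
  }
  d <- dim(I)
  I <- .withSeed(.deriveSeed(seed, "camera-noise"), {
    v <- as.numeric(I)
    if (shot) v <- stats::rpois(length(v), v)
    if (readSigma > 0) v <- v + stats::rnorm(length(v), 0, readSigma)
    v
  })
  I <- pmin(pmax(round(I), 0), 2^bitDepth - 1)
  dim(I) <- d
  speckleFrame(I, pitch = frame@pitch, exposure = frame@exposure,
               meta = c(frame@meta, list(noisy = TRUE, bitDepth = bitDepth)))
}

setMethod("show", "SpeckleFrame", function(object) {
  d <- dim(object@intensity)
  m <- mean(object@intensity)
  cat(sprintf("SpeckleFrame %dx%d px (pitch %g mm), mean %.4g, contrast %.3f\n",
              d[1], d[2], object@pitch, m,
              if (m > 0) stats::sd(object@intensity) / m else NA_real_))
})
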