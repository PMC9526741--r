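# Mean-subtracted FFT correlations of speckle frames: autocorrelation
# imaging, cross-correlation between times, the background-cancelling
# differential correlation, and the model-predicted autocorrelation
# (object autocorrelation blurred by the memory kernel).
#
# All correlations are linear (zero-padded), never circular: speckle frames
# are not periodic and circular wrap-around would create false lobes.  For
# n x n input the lag map is (2n-1) x (2n-1) with zero lag at index (n, n).
# Convention: map(l) = sum_x a(x) * b(x + l), frame_a the later frame.

# Pre-process one frame for correlation: subtract the mean, optionally
# apply a Tukey window, re-subtract the residual mean so the processed
# image sums exactly to zero (which makes every correlation map sum to
# zero exactly -- the discrete counterpart of the zero-mean property of
# the differential correlation).
.prepFrame <- function(I, window, alpha) {
  if (stats::sd(I) == 0)
    stop("degenerate frame: zero variance (constant image)", call. = FALSE)
  x <- I - mean(I)
  if (window == "tukey") {
    x <- x * .tukey2(dim(x), alpha)
    x <- x - mean(x)
  }
  x
}

.asIntensity <- function(frame) {
  if (methods::is(frame, "SpeckleFrame")) frame@intensity
  else .assertMatrix(frame, "frame")
}

.framePitch <- function(frame, pitch) {
  if (methods::is(frame, "SpeckleFrame")) frame@pitch
  else if (!is.null(pitch)) pitch else 1
}

.makeMap <- function(vals, pitch, kind, normalize, window, meta = list()) {
  n <- (dim(vals) + 1L) %/% 2L
  methods::new("CorrelationMap", values = vals, pitch = pitch, kind = kind,
               normalization = normalize, window = window,
               center = as.integer(n), meta = meta)
}

#' Autocorrelation of a speckle frame
#'
#' Mean-subtracted, optionally windowed, zero-padded FFT autocorrelation.
#' Within the memory range the ensemble-averaged speckle autocorrelation is
#' proportional to the hidden object's autocorrelation blurred by the
#' memory kernel, which is what makes the hidden object's structure visible
#' in a single speckle frame.  Always centrosymmetric, with its global
#' maximum at zero lag.
#'
#' @param frame A [SpeckleFrame-class] or a numeric matrix (at least 2 x 2,
#'   finite, non-constant).
#' @param window "none" (default; keeps identity-based cancellations exact)
#'   or "tukey" (tapered cosine, suppresses edge artifacts).
#' @param normalize "coeff" (default; divides by the processed input norms
#'   so values lie in \[-1, 1\]) or "raw" (plain lag sums).
#' @param alpha Tukey taper fraction.
#' @param pitch Lag pitch override (mm/px) when `frame` is a bare matrix.
#' @return A [CorrelationMap-class] of kind "auto".
#' @export
autocorrelate <- function(frame, window = c("none", "tukey"),
                          normalize = c("coeff", "raw"), alpha = 0.25,
                          pitch = NULL) {
  window <- match.arg(window); normalize <- match.arg(normalize)
  I <- .asIntensity(frame)
  if (any(dim(I) < 2)) stop("frame must be at least 2x2", call. = FALSE)
  x <- .prepFrame(I, window, alpha)
  vals <- .xcorrCore(x, x)
  if (normalize == "coeff") vals <- vals / sum(x * x)
  .makeMap(vals, .framePitch(frame, pitch), "auto", normalize, window)
}

#' Cross-correlation between two speckle frames
#'
#' Correlates the (later) frame at t1 with the (reference) frame at t0.
#' For a scene of independently moving sub-objects the map decomposes into
#' a static part (all static-pair correlations, identical to the
#' autocorrelation's static part) plus a moving part (the moving object's
#' cross-correlations with every sub-object), which translates with the
#' object: rigid scene motion between the frames translates the whole
#' autocorrelation by the detector-mapped displacement.
#' \code{crossCorrelate(f, f)} equals \code{autocorrelate(f)} exactly.
#'
#' @param frame_a Frame at t1 (the later frame).
#' @param frame_b Frame at t0 (the reference frame); same shape and pitch.
#' @inheritParams autocorrelate
#' @return A [CorrelationMap-class] of kind "cross".
#' @export
crossCorrelate <- function(frame_a, frame_b, window = c("none", "tukey"),
                           normalize = c("coeff", "raw"), alpha = 0.25,
                           pitch = NULL) {
  window <- match.arg(window); normalize <- match.arg(normalize)
  Ia <- .asIntensity(frame_a); Ib <- .asIntensity(frame_b)
  if (!identical(dim(Ia), dim(Ib)))
    stop("frames must have identical shapes", call. = FALSE)
  pa <- .framePitch(frame_a, pitch); pb <- .framePitch(frame_b, pitch)
  if (abs(pa - pb) > 1e-12) stop("frames must share the same pitch",
                                 call. = FALSE)
  if (any(dim(Ia) < 2)) stop("frames must be at least 2x2", call. = FALSE)
  xa <- .prepFrame(Ia, window, alpha)
  xb <- .prepFrame(Ib, window, alpha)
  vals <- .xcorrCore(xa, xb)
  if (normalize == "coeff") vals <- vals / sqrt(sum(xa * xa) * sum(xb * xb))
  .makeMap(vals, pa, "cross", normalize, window)
}

#' Differential correlation: cross minus auto
#'
#' \code{crossCorrelate(t1, t0) - autocorrelate(t1)}.  Every correlation
#' term between static sub-objects appears identically in both and cancels,
#' so for a static scene the map is zero up to noise; for identical frames
#' it is exactly the zero map.  For one intensity-conserving moving
#' sub-object the map reduces to the cross-correlation of (old minus new
#' object) with the current scene, blurred by the memory kernel: positive
#' lobes at the static background's lags relative to the object's old
#' position, negative lobes relative to its new position, zero total sum.
#' The moving object is thereby shown in its own frame of reference, with
#' the static background lobes drifting around it.
#'
#' @inheritParams crossCorrelate
#' @return A [CorrelationMap-class] of kind "differential".
#' @export
differentialCorrelation <- function(frame_a, frame_b,
                                    window = c("none", "tukey"),
                                    normalize = c("coeff", "raw"),
                                    alpha = 0.25, pitch = NULL) {
  window <- match.arg(window); normalize <- match.arg(normalize)
  Ia <- .asIntensity(frame_a); Ib <- .asIntensity(frame_b)
  if (!identical(dim(Ia), dim(Ib)))
    stop("frames must have identical shapes", call. = FALSE)
  pa <- .framePitch(frame_a, pitch)
  xa <- .prepFrame(Ia, window, alpha)
  xb <- .prepFrame(Ib, window, alpha)
  # same windowing path and one *common* normalization factor for both
  # terms: the static background then cancels identically (independent of
  # small norm differences between the frames), and the map is bit-for-bit
  # zero for identical frames
  cross <- .xcorrCore(xa, xb)
  auto <- .xcorrCore(xa, xa)
  vals <- cross - auto
  if (normalize == "coeff")
    vals <- vals / sqrt(sum(xa * xa) * sum(xb * xb))
  .makeMap(vals, pa, "differential", normalize, window)
}

#' Model-predicted speckle autocorrelation of a scene
#'
#' The ensemble-averaged (over screen disorder) autocorrelation of the
#' measured speckle is proportional to the object autocorrelation convolved
#' with the memory kernel.  This computes that prediction on the detector
#' lag grid: every pair of lit object pixels contributes, at its
#' detector-mapped separation, a Gaussian lobe of width set by the
#' diffraction limit of the illumination beam, weighted by the intensity
#' product and the memory envelope at the pair separation.  The output is
#' defined up to an arbitrary positive scale.
#'
#' @param scene An [ObjectScene-class].
#' @param kernel A [MemoryKernel-class].
#' @param frameDim Detector frame size (rows, cols) whose (2n-1) lag grid
#'   the prediction is evaluated on.
#' @param maxPairs Safety cap on the number of distinct object-pixel pairs.
#' @return A [CorrelationMap-class] of kind "auto" (normalization
#'   "raw"; arbitrary scale).
#' @export
predictedAutocorrelation <- function(scene, kernel, frameDim,
                                     maxPairs = 40000L) {
  cfg <- kernel@config
  frameDim <- as.integer(rep(frameDim, length.out = 2))
  k <- waveNumber(cfg)
  lit <- which(scene@intensity > 0, arr.ind = TRUE)
  if (nrow(lit) == 0) stop("scene is empty", call. = FALSE)
  if (nrow(lit)^2 > maxPairs)
    stop("scene has too many lit pixels for a pairwise prediction (",
         nrow(lit), "^2 pairs); coarsen the object grid", call. = FALSE)
  d <- dim(scene@intensity)
  cx <- floor(d[2] / 2) + 1L; cy <- floor(d[1] / 2) + 1L
  px <- (lit[, 2] - cx) * scene@pitch
  py <- (lit[, 1] - cy) * scene@pitch
  w <- scene@intensity[lit]
  nl <- 2L * frameDim - 1L
  lagx <- .axis0(nl[2], cfg@detectorPitch)
  lagy <- .axis0(nl[1], cfg@detectorPitch)
  out <- matrix(0, nl[1], nl[2])
  sig <- cfg@L_s / (k * cfg@sigma)   # Gaussian 1/e half-width on the lag grid
  n <- length(w)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dxo <- c(px[i] - px[j], py[i] - py[j])
    env <- memoryEnvelope(k * .vlen(dxo) * cfg@L / cfg@L_o)
    if (env < 1e-12) next
    mu <- objectToDetectorShift(dxo, cfg)
    gx <- exp(-((lagx - mu[1]) / sig)^2)
    gy <- exp(-((lagy - mu[2]) / sig)^2)
    out <- out + (w[i] * w[j] * env) * outer(gy, gx)
  }
  .makeMap(out, cfg@detectorPitch, "auto", "raw", "none",
           meta = list(predicted = TRUE))
}

#' Ensemble-averaged autocorrelation over independent screens
#'
#' Mean of the per-frame autocorrelations of frames of the same scene
#' rendered through independent screen realizations; the off-peak
#' fluctuations shrink as 1/sqrt(N) and the mean converges to the
#' model-predicted autocorrelation.
#'
#' @param frameList List of [SpeckleFrame-class] (or matrices) of one scene
#'   over independent screens.
#' @inheritParams autocorrelate
#' @return A [CorrelationMap-class] of kind "auto".
#' @export
ensembleAutocorrelation <- function(frameList, window = c("none", "tukey"),
                                    normalize = c("coeff", "raw"),
                                    alpha = 0.25, pitch = NULL) {
  window <- match.arg(window); normalize <- match.arg(normalize)
  if (length(frameList) < 1) stop("need at least one frame", call. = FALSE)
  maps <- lapply(frameList, autocorrelate, window = window,
                 normalize = normalize, alpha = alpha, pitch = pitch)
  dims <- vapply(maps, function(m) dim(m@values), integer(2))
  if (any(dims != dims[, 1])) stop("frames have inconsistent shapes",
                                   call. = FALSE)
  vals <- Reduce(`+`, lapply(maps, function(m) m@values)) / length(maps)
  .makeMap(vals, maps[[1]]@pitch, "auto", normalize, window,
           meta = list(nFrames = length(maps)))
}

#' Lag coordinates of a correlation map
#'
#' @param map A [CorrelationMap-class].
#' @return List with numeric vectors \code{x} and \code{y}: the lag (mm) of
#'   each column / row.
#' @export
lagAxes <- function(map) {
  d <- dim(map@values)
  list(x = (seq_len(d[2]) - map@center[2]) * map@pitch,
       y = (seq_len(d[1]) - map@center[1]) * map@pitch)
}

setMethod("show", "CorrelationMap", function(object) {
  d <- dim(object@values)
  cat(sprintf(paste0("CorrelationMap (%s) %dx%d lags (pitch %g mm), ",
                     "window %s, normalization %s\n  range [%.4g, %.4g]\n"),
              object@kind, d[1], d[2], object@pitch, object@window,
              object@normalization, min(object@values), max(object@values)))
})
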