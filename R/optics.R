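# Memory-effect kernel and the object-plane <-> detector-plane geometry.

#' Construct an optical configuration
#'
#' Defaults reproduce the reference experiment geometry: a He-Ne source
#' (632.8 nm), object plane 430 mm behind the scattering layer, detector
#' 50 mm in front of it, so object motion appears on the detector scaled by
#' \code{L_s / L_o = 50/430} and with reversed axes (pinhole-style).
#'
#' @param wavelength Wavelength (mm). Default 632.8e-6 (He-Ne).
#' @param sigma Illumination Gaussian width (mm); the beam intensity profile
#'   on the layer is \eqn{\exp(-|\xi|^2/(2\sigma^2))} (variance
#'   \eqn{\sigma^2}). Default 0.3.
#' @param L Scattering-layer thickness (mm). Default 0.01 (thin ground-glass
#'   regime, essentially unlimited memory range over the simulated field of
#'   view); see [thicknessForMemoryRange()] to emulate a thicker layer.
#' @param L_o Object-to-layer distance (mm). Default 430.
#' @param L_s Layer-to-detector distance (mm). Default 50.
#' @param detectorPitch Detector pixel pitch (mm/px). Default 0.008.
#' @param objectPitch Object-plane pitch (mm/px). Defaults to
#'   \code{detectorPitch * L_o / L_s} so that one object-plane pixel of
#'   motion maps onto one detector pixel of correlation shift.
#' @param flipAxes Whether the detector image is axis-reversed relative to
#'   the hidden scene (TRUE for the lensless pinhole-like geometry).
#' @return An [OpticalConfig-class].
#' @examples
#' cfg <- opticalConfig()
#' objectToDetectorShift(c(4.3, 0), cfg)   # -> (-0.5, 0) mm on the detector
#' @export
opticalConfig <- function(wavelength = 632.8e-6, sigma = 0.3, L = 0.01,
                          L_o = 430, L_s = 50,
                          detectorPitch = 0.008,
                          objectPitch = detectorPitch * L_o / L_s,
                          flipAxes = TRUE) {
  methods::new("OpticalConfig",
    wavelength = wavelength, sigma = sigma, L = L, L_o = L_o, L_s = L_s,
    objectPitch = objectPitch, detectorPitch = detectorPitch,
    flipAxes = flipAxes)
}

#' @describeIn opticalConfig Wavenumber \eqn{k = 2\pi/\lambda} (1/mm).
#' @param config An [OpticalConfig-class].
#' @export
waveNumber <- function(config) 2 * pi / config@wavelength

#' Memory-effect angular decorrelation envelope
#'
#' The speckle intensity correlation surviving an illumination tilt
#' \eqn{|\Delta\theta|} through a layer of thickness L decays as
#' \eqn{(x/\sinh x)^2} with \eqn{x = k|\Delta\theta|L}.  Continuous at 0
#' (value 1), strictly decreasing; returns 0 once \eqn{\sinh} would overflow
#' (x > 700, where the true value is below 1e-300).
#'
#' @param x Nonnegative dimensionless argument \eqn{k|\Delta\theta|L}
#'   (absolute value is taken). Vectorized.
#' @return Values in \[0, 1\].
#' @examples
#' memoryEnvelope(0)          # 1
#' memoryEnvelope(1)          # (1/sinh 1)^2 ~ 0.724
#' @export
memoryEnvelope <- function(x) {
  x <- abs(x)
  out <- numeric(length(x))
  big <- x > 700
  tiny <- x < 1e-8 & !big
  mid <- !big & !tiny
  out[tiny] <- 1
  out[mid] <- (x[mid] / sinh(x[mid]))^2
  out[big] <- 0
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Construct the memory-effect kernel for a configuration
#' @param config An [OpticalConfig-class].
#' @return A [MemoryKernel-class].
#' @export
memoryKernel <- function(config) methods::new("MemoryKernel", config = config)

#' Evaluate the memory-effect correlation kernel
#'
#' Speckle intensity correlation between sources separated by \code{dx_o} on
#' the object plane, at detector-plane lag \code{dx_d}:
#' \deqn{C = \exp(-k^2 |\Delta\theta_o - \Delta\theta_d|^2 \sigma^2)\,
#'       \left(\frac{k|\Delta\theta_o|L}{\sinh(k|\Delta\theta_o|L)}\right)^2}
#' with \eqn{\Delta\theta_o = dx_o / L_o} and \eqn{\Delta\theta_d = dx_d /
#' L_s} (angular interpretation, which makes the exponent dimensionless and
#' places the Gaussian peak where the detector lag matches the geometrically
#' scaled object lag).  Equals 1 at (0, 0).
#'
#' @param dx_o Object-plane lag vector (x, y) in mm.
#' @param dx_d Detector-plane lag vector (x, y) in mm.
#' @param kernel A [MemoryKernel-class].
#' @return Scalar correlation in \[0, 1\].
#' @examples
#' k <- memoryKernel(opticalConfig())
#' kernelValue(c(0, 0), c(0, 0), k)  # 1
#' @export
kernelValue <- function(dx_o, dx_d, kernel) {
  cfg <- kernel@config
  k <- waveNumber(cfg)
  th_o <- dx_o / cfg@L_o
  th_d <- dx_d / cfg@L_s
  g <- exp(-k^2 * sum((th_o - th_d)^2) * cfg@sigma^2)
  g * memoryEnvelope(k * .vlen(th_o) * cfg@L)
}

#' Map an object-plane displacement to the detector plane
#'
#' Motion of a hidden object appears in the correlation maps scaled by
#' \code{L_s / L_o} and, for the pinhole-like geometry (\code{flipAxes}),
#' with reversed axes.  Exact linear map; inverse of
#' [detectorToObjectShift()].
#'
#' @param d_obj Object-plane displacement (x, y) in mm.
#' @param config An [OpticalConfig-class].
#' @return Detector-plane displacement (x, y) in mm.
#' @export
objectToDetectorShift <- function(d_obj, config) {
  s <- if (config@flipAxes) -1 else 1
  s * d_obj * config@L_s / config@L_o
}

#' @rdname objectToDetectorShift
#' @param d_det Detector-plane displacement (x, y) in mm.
#' @export
detectorToObjectShift <- function(d_det, config) {
  s <- if (config@flipAxes) -1 else 1
  s * d_det * config@L_o / config@L_s
}

#' Expected speckle grain diameter on the detector
#'
#' The far-field speckle grain scales as \eqn{\lambda L_s / D} with D the
#' illuminated spot diameter on the layer; used to assert the simulation is
#' sampled with at least 2 detector pixels per grain.
#'
#' @param config An [OpticalConfig-class].
#' @param illuminatedDiameter Illuminated spot diameter on the layer (mm).
#'   Defaults to \code{4 * sigma} (the practical extent of the Gaussian
#'   beam).
#' @return Grain diameter (mm).  Errors if the configuration is undersampled
#'   (grain smaller than 2 detector pixels).
#' @export
expectedGrainDiameter <- function(config,
                                  illuminatedDiameter = 4 * config@sigma) {
  if (illuminatedDiameter <= 0)
    stop("'illuminatedDiameter' must be positive", call. = FALSE)
  g <- config@wavelength * config@L_s / illuminatedDiameter
  if (g < 2 * config@detectorPitch)
    stop(sprintf(paste0(
      "undersampled configuration: expected grain diameter %.3g mm < 2 ",
      "detector pixels (%.3g mm); reduce the detector pitch or the ",
      "illumination width"), g, 2 * config@detectorPitch), call. = FALSE)
  g
}

# x at which the memory envelope has dropped to 1/2 (solved once).
.envHalfX <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- stats::uniroot(function(x) memoryEnvelope(x) - 0.5,
                               c(0.5, 3), tol = 1e-12)$root
    cache
  }
})

#' Memory-effect range on the object plane
#'
#' Object-plane separation at which the memory envelope drops to 1/2:
#' \eqn{r = x_{1/2} L_o / (k L)} with \eqn{x_{1/2} \approx 1.49}.
#'
#' @param config An [OpticalConfig-class].
#' @return Half-correlation separation (mm).
#' @export
memoryRange <- function(config) {
  .envHalfX() * config@L_o / (waveNumber(config) * config@L)
}

#' @rdname memoryRange
#' @param range_mm Desired object-plane memory range (mm).
#' @return For \code{thicknessForMemoryRange}: the layer thickness L (mm)
#'   that yields the requested range.
#' @export
thicknessForMemoryRange <- function(config, range_mm) {
  if (range_mm <= 0) stop("'range_mm' must be positive", call. = FALSE)
  .envHalfX() * config@L_o / (waveNumber(config) * range_mm)
}

# ---- flat key-value serialization --------------------------------------

.optKeys <- c("wavelength_mm", "sigma_mm", "L_mm", "L_o_mm", "L_s_mm",
              "object_pitch_mm", "detector_pitch_mm", "flip_axes")

#' Read / write an optical configuration as a flat key-value file
#'
#' Plain-text YAML with documented keys \code{wavelength_mm, sigma_mm, L_mm,
#' L_o_mm, L_s_mm, object_pitch_mm, detector_pitch_mm, flip_axes}.  Unknown
#' keys are rejected; missing keys fall back to the [opticalConfig()]
#' defaults.
#'
#' @param path File path.
#' @return For \code{readOpticalConfig}, an [OpticalConfig-class].
#' @export
readOpticalConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  kv <- yaml::read_yaml(path)
  unknown <- setdiff(names(kv), .optKeys)
  if (length(unknown))
    stop("unknown optical config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  d <- opticalConfig()
  pick <- function(key, dflt) if (!is.null(kv[[key]])) kv[[key]] else dflt
  opticalConfig(
    wavelength    = pick("wavelength_mm", d@wavelength),
    sigma         = pick("sigma_mm", d@sigma),
    L             = pick("L_mm", d@L),
    L_o           = pick("L_o_mm", d@L_o),
    L_s           = pick("L_s_mm", d@L_s),
    detectorPitch = pick("detector_pitch_mm", d@detectorPitch),
    objectPitch   = pick("object_pitch_mm",
                         pick("detector_pitch_mm", d@detectorPitch) *
                           pick("L_o_mm", d@L_o) / pick("L_s_mm", d@L_s)),
    flipAxes      = isTRUE(pick("flip_axes", d@flipAxes)))
}

#' @rdname readOpticalConfig
#' @param config An [OpticalConfig-class] to serialize.
#' @export
writeOpticalConfig <- function(config, path) {
  yaml::write_yaml(list(
    wavelength_mm     = config@wavelength,
    sigma_mm          = config@sigma,
    L_mm              = config@L,
    L_o_mm            = config@L_o,
    L_s_mm            = config@L_s,
    object_pitch_mm   = config@objectPitch,
    detector_pitch_mm = config@detectorPitch,
    flip_axes         = config@flipAxes), path)
  invisible(path)
}

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig\n")
  cat(sprintf("  wavelength: %g mm   sigma: %g mm   L: %g mm\n",
              object@wavelength, object@sigma, object@L))
  cat(sprintf("  L_o: %g mm   L_s: %g mm   scale L_s/L_o: %.4g\n",
              object@L_o, object@L_s, object@L_s / object@L_o))
  cat(sprintf("  pitches: object %g, detector %g mm/px   flipAxes: %s\n",
              object@objectPitch, object@detectorPitch, object@flipAxes))
  cat(sprintf("  memory range (object plane): %.3g mm\n", memoryRange(object)))
})

setMethod("show", "MemoryKernel", function(object) {
  cat("MemoryKernel on:\n")
  show(object@config)
})
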