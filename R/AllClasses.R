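# S4 class definitions for the speckle tracking pipeline.
#
# Coordinate conventions used by every class and function in the package:
#  * grids are R matrices indexed [row, col];
#  * all 2-vectors (positions, shifts, lags) are (x, y) in mm, where
#    x runs along columns and y along rows (increasing row = increasing y);
#  * the origin of a grid of size n sits at index floor(n/2) + 1 on each
#    axis (the FFT centre convention), so positions in mm are
#    (index - centre) * pitch.

#' Optical geometry of a speckle tracking experiment
#'
#' Holds every geometric and physical parameter of the imaging-through-
#' scattering geometry: a hidden object plane at distance \code{L_o} behind a
#' thin scattering layer of thickness \code{L}, a lensless detector at
#' distance \code{L_s} on the other side, and a spatially incoherent,
#' narrow-band illumination whose intensity profile on the layer is Gaussian
#' with variance \code{sigma^2}.
#'
#' @slot wavelength Illumination wavelength (mm).
#' @slot sigma Illumination Gaussian width (mm); the beam intensity profile
#'   on the scattering layer is \eqn{\exp(-|\xi|^2 / (2\sigma^2))}.
#' @slot L Scattering-layer thickness (mm); controls the memory-effect range.
#' @slot L_o Object-plane to scattering-layer distance (mm).
#' @slot L_s Scattering-layer to detector distance (mm).
#' @slot objectPitch Object-plane sampling pitch (mm/pixel).
#' @slot detectorPitch Detector pixel pitch (mm/pixel).
#' @slot flipAxes Logical; if \code{TRUE} (the default geometry) the speckle
#'   image axes are reversed relative to the hidden scene, as in a pinhole
#'   camera, and displacement mapping accounts for the reversal.
#'
#' @seealso [opticalConfig()], [memoryKernel()], [objectToDetectorShift()]
#' @export
setClass("OpticalConfig",
  representation(
    wavelength    = "numeric",
    sigma         = "numeric",
    L             = "numeric",
    L_o           = "numeric",
    L_s           = "numeric",
    objectPitch   = "numeric",
    detectorPitch = "numeric",
    flipAxes      = "logical"
  ),
  validity = function(object) {
    msg <- character()
    for (s in c("wavelength", "sigma", "L", "L_o", "L_s",
                "objectPitch", "detectorPitch")) {
      v <- slot(object, s)
      if (length(v) != 1 || !is.finite(v) || v <= 0)
        msg <- c(msg, sprintf("'%s' must be a single strictly positive number", s))
    }
    if (length(object@flipAxes) != 1 || is.na(object@flipAxes))
      msg <- c(msg, "'flipAxes' must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
  }
)

#' Memory-effect correlation kernel
#'
#' Closed-form speckle intensity correlation between two incoherent source
#' points separated by \code{dx_o} on the object plane, evaluated at a
#' detector-plane lag \code{dx_d}: a Gaussian factor sharply peaked where the
#' detector lag matches the geometrically scaled object lag, times the
#' memory-effect envelope \eqn{(x/\sinh x)^2} with
#' \eqn{x = k |\Delta\theta| L}.  Normalized to 1 at (0, 0); it acts as the
#' point spread function of autocorrelation imaging.
#'
#' @slot config An [OpticalConfig-class] supplying \eqn{k}, \eqn{\sigma},
#'   \eqn{L} and the distances.
#' @seealso [memoryKernel()], [kernelValue()], [memoryEnvelope()]
#' @export
setClass("MemoryKernel",
  representation(config = "OpticalConfig"))

#' A single component of a hidden scene
#'
#' A hidden scene is a sum of sub-objects, each a small nonnegative intensity
#' sprite anchored at an object-plane position.  Sub-objects flagged mobile
#' are re-rasterized every frame from the pristine sprite (translation,
#' rotation, scaling), with the total intensity renormalized so rigid motion
#' conserves the radiated power.
#'
#' @slot sprite Nonnegative numeric matrix (arbitrary intensity units).
#' @slot anchor Object-plane position (x, y) of the sprite centre (mm).
#' @slot mobile Logical; whether this sub-object is allowed to move.
#' @slot label Character tag used in printouts.
#' @export
setClass("SubObject",
  representation(
    sprite = "matrix",
    anchor = "numeric",
    mobile = "logical",
    label  = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@sprite) || any(!is.finite(object@sprite)) ||
        any(object@sprite < 0))
      msg <- c(msg, "'sprite' must be a finite nonnegative numeric matrix")
    if (length(object@anchor) != 2 || any(!is.finite(object@anchor)))
      msg <- c(msg, "'anchor' must be a finite length-2 vector (mm)")
    if (length(msg)) msg else TRUE
  }
)

#' Hidden-plane intensity map
#'
#' The hidden scene at one instant: a nonnegative intensity grid (the
#' rasterized sum of its sub-objects) plus the sub-object decomposition.
#'
#' @slot intensity Nonnegative numeric matrix, the radiated intensity.
#' @slot pitch Object-plane pitch (mm/pixel).
#' @slot subObjects List of [SubObject-class].
#' @export
setClass("ObjectScene",
  representation(
    intensity  = "matrix",
    pitch      = "numeric",
    subObjects = "list"
  ),
  validity = function(object) {
    msg <- character()
    if (any(!is.finite(object@intensity)) || any(object@intensity < 0))
      msg <- c(msg, "'intensity' must be finite and nonnegative")
    if (length(object@pitch) != 1 || object@pitch <= 0)
      msg <- c(msg, "'pitch' must be a single positive number (mm/px)")
    if (length(msg)) msg else TRUE
  }
)

#' Time-ordered sequence of hidden scenes
#'
#' @slot frames List of [ObjectScene-class], all sharing grid shape and pitch.
#' @slot frameInterval Time between frames (arbitrary units, metadata only).
#' @slot motion List (possibly empty) recording the per-frame motion applied
#'   to each sub-object, as stored by [applyMotion()].
#' @export
setClass("SceneSequence",
  representation(
    frames        = "list",
    frameInterval = "numeric",
    motion        = "list"
  ),
  validity = function(object) {
    if (length(object@frames) == 0) return("'frames' must be non-empty")
    dims <- vapply(object@frames, function(f) dim(f@intensity), integer(2))
    if (any(dims != dims[, 1]))
      return("all frames must share the same grid shape")
    p <- vapply(object@frames, function(f) f@pitch, numeric(1))
    if (any(abs(p - p[1]) > 1e-12)) return("all frames must share the same pitch")
    TRUE
  }
)

#' Virtual parent of the two scattering-screen backends
#'
#' A screen fixes the random realization of the scattering layer.  It is
#' static across a sequence (as a physical layer is) and deterministic given
#' its seed.  Two concrete backends exist: [PhysicalScreen-class] (thin
#' random phase screen, angular-spectrum propagation, effectively unlimited
#' memory range) and [SpectralScreen-class] (correlated-field synthesis that
#' imposes the finite memory-effect envelope directly).
#'
#' @slot seed Integer seed the realization was drawn from.
#' @slot frameDim Detector frame size (rows, cols) the screen was built for.
#' @slot config The [OpticalConfig-class] the screen was built for.
#' @export
setClass("ScatteringScreen",
  representation("VIRTUAL",
    seed     = "integer",
    frameDim = "integer",
    config   = "OpticalConfig"
  )
)

#' Thin random phase screen (physical backend)
#'
#' @slot phase Random phase grid in \[0, 2pi), on the padded simulation grid.
#' @export
setClass("PhysicalScreen",
  contains = "ScatteringScreen",
  representation(phase = "matrix"))

#' Correlated-field screen (statistical backend)
#'
#' Synthesizes, for every object-plane source position, a screen field that
#' is a fixed weighted sum of independent white complex Gaussian fields with
#' position-dependent phase factors.  The weights sample the 2-D spectral
#' density of the target field correlation (the square root of the memory
#' envelope, by the Siegert relation), so the realized pairwise intensity
#' correlations between any two source positions follow the memory-effect
#' kernel, while a fixed position always reproduces the identical speckle.
#'
#' @slot fields Complex matrix (grid pixels x components), the white fields.
#' @slot qx,qy Angular frequencies of each component (in scaled angle units).
#' @slot weights Nonnegative spectral weights, summing to 1.
#' @slot screenPitch Screen-plane sampling pitch (mm) of the padded grid.
#' @slot thetaExtent Maximum object-plane source separation (mm) the spectral
#'   grid resolves without wrap-around.
#' @export
setClass("SpectralScreen",
  contains = "ScatteringScreen",
  representation(
    fields      = "matrix",
    qx          = "numeric",
    qy          = "numeric",
    weights     = "numeric",
    screenPitch = "numeric",
    thetaExtent = "numeric"
  )
)

#' A detector-plane speckle frame
#'
#' The only observable of the method: the nonnegative intensity recorded by
#' the lensless camera.
#'
#' @slot intensity Nonnegative numeric matrix.
#' @slot pitch Detector pixel pitch (mm/pixel).
#' @slot exposure Exposure time metadata (seconds; no intra-frame motion blur
#'   is simulated).
#' @slot meta List of free-form metadata (seed, backend, scene tag, ...).
#' @export
setClass("SpeckleFrame",
  representation(
    intensity = "matrix",
    pitch     = "numeric",
    exposure  = "numeric",
    meta      = "list"
  ),
  validity = function(object) {
    msg <- character()
    if (any(!is.finite(object@intensity)) || any(object@intensity < 0))
      msg <- c(msg, "'intensity' must be finite and nonnegative")
    if (length(object@pitch) != 1 || object@pitch <= 0)
      msg <- c(msg, "'pitch' must be a single positive number (mm/px)")
    if (length(msg)) msg else TRUE
  }
)

#' A correlation lag map
#'
#' Real-valued map over detector-plane lag, zero lag at the grid centre
#' (index (n, n) of the (2n-1)-sized map for n x n input frames).
#'
#' @slot values Numeric matrix over lag.
#' @slot pitch Lag pitch (mm/pixel, equal to the detector pitch).
#' @slot kind One of "auto", "cross", "differential".
#' @slot normalization "raw" (plain sums) or "coeff" (normalized by the input
#'   norms, values in \[-1, 1\]).
#' @slot window Window applied before correlating ("none" or "tukey").
#' @slot center Integer (row, col) index of zero lag.
#' @slot meta List of metadata.
#' @export
setClass("CorrelationMap",
  representation(
    values        = "matrix",
    pitch         = "numeric",
    kind          = "character",
    normalization = "character",
    window        = "character",
    center        = "integer",
    meta          = "list"
  ),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("auto", "cross", "differential"))
      msg <- c(msg, "'kind' must be one of auto/cross/differential")
    if (length(object@center) != 2)
      msg <- c(msg, "'center' must be a length-2 integer index")
    if (length(msg)) msg else TRUE
  }
)

#' A paired positive/negative lobe in a differential correlation map
#'
#' For an intensity-conserving moving sub-object, the differential
#' correlation carries positive lobes at the lags of the static background
#' relative to the object's old position and negative lobes relative to its
#' new position; the vector from a positive lobe to its paired negative lobe
#' is the detector-plane displacement of the mover.
#'
#' @slot posLobe,negLobe Lag positions (x, y) in mm of the paired lobes.
#' @slot posAmp,negAmp Lobe amplitudes (posAmp > 0 > negAmp).
#' @slot displacementDet Detector-plane displacement (mm): negLobe - posLobe.
#' @slot snr Smaller lobe amplitude over the map's robust noise level.
#' @slot refined Logical; FALSE if the subpixel fit fell back to the integer
#'   peak (map border or degenerate curvature).
#' @export
setClass("MotionFeature",
  representation(
    posLobe         = "numeric",
    negLobe         = "numeric",
    posAmp          = "numeric",
    negAmp          = "numeric",
    displacementDet = "numeric",
    snr             = "numeric",
    refined         = "logical"
  )
)

#' A tracked trajectory
#'
#' Per-frame object-plane displacement estimates chained into a cumulative
#' track.  Only relative motion is observable (autocorrelations are
#' centrosymmetric), so the track starts at the origin by convention.
#'
#' @slot table data.frame with columns frame, dx_mm, dy_mm, cum_x_mm,
#'   cum_y_mm, ref_lag, snr, valid.
#' @slot pitchObj Object-plane pitch (mm/px) used for reporting.
#' @export
setClass("Trajectory",
  representation(table = "data.frame", pitchObj = "numeric"))
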