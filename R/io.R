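# Image-stack, trajectory and rendering I/O.
#
# Speckle stacks travel as multi-page grayscale TIFF (8/16/32-bit
# unsigned samples) with a plain-text YAML sidecar (<path>.yml) carrying
# the pixel pitch and a power-of-two intensity scale.  At 32 bits the
# round-trip quantization is 2^-32 of full scale (relative error below
# 1e-9), the best the TIFF integer sample formats provide.

.sidecarPath <- function(path) paste0(path, ".yml")

#' Write a stack of speckle frames as multi-page TIFF
#'
#' @param frameList List of [SpeckleFrame-class] or numeric matrices.
#' @param path Output TIFF path.
#' @param bitsPerSample Unsigned sample width: 32 (default; quantization
#'   2^-32 of full scale), 16 or 8.
#' @param pitch Pixel pitch (mm/px); taken from the frames if omitted.
#' @param meta Extra key-value metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
writeStack <- function(frameList, path, bitsPerSample = 32, pitch = NULL,
                       meta = list()) {
  if (!bitsPerSample %in% c(8, 16, 32))
    stop("'bitsPerSample' must be 8, 16 or 32", call. = FALSE)
  mats <- lapply(frameList, .asIntensity)
  if (is.null(pitch)) {
    p <- vapply(frameList, .framePitch, numeric(1), pitch = NULL)
    if (length(unique(p)) > 1) stop("frames have inconsistent pitches",
                                    call. = FALSE)
    pitch <- p[1]
  }
  mx <- max(1e-300, max(vapply(mats, max, numeric(1))))
  # power-of-two scale: division is exact in binary floating point, so
  # the only loss is the TIFF sample quantization itself; the sidecar
  # stores the integer exponent, which YAML serializes exactly
  e2 <- as.integer(ceiling(log2(mx)))
  mats <- lapply(mats, function(m) m / 2^e2)
  tiff::writeTIFF(mats, path, bits.per.sample = bitsPerSample)
  yaml::write_yaml(c(list(pitch_mm = pitch, intensity_scale_log2 = e2,
                          n_frames = length(mats),
                          bits_per_sample = bitsPerSample), meta),
                   .sidecarPath(path))
  invisible(path)
}

#' Read a stack of speckle frames from multi-page TIFF
#'
#' @param path TIFF path; a sidecar `<path>.yml` (as written by
#'   [writeStack()]) supplies the pitch and intensity scale.
#' @param pitch Pitch override (mm/px); required when no sidecar exists
#'   (there is no silent default).
#' @return List of [SpeckleFrame-class].
#' @export
readStack <- function(path, pitch = NULL) {
  if (!file.exists(path)) stop("stack not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1
  if (file.exists(.sidecarPath(path))) {
    sc <- yaml::read_yaml(.sidecarPath(path))
    if (is.null(pitch)) pitch <- sc$pitch_mm
    if (!is.null(sc$intensity_scale_log2)) scale <- 2^sc$intensity_scale_log2
  }
  if (is.null(pitch))
    stop("no pixel pitch available: provide 'pitch' or a sidecar ",
         .sidecarPath(path), call. = FALSE)
  dims <- vapply(pages, function(p) length(dim(p)), integer(1))
  if (any(dims != 2))
    stop("stack must be grayscale (single-channel); got a multi-channel ",
         "image", call. = FALSE)
  shp <- vapply(pages, dim, integer(2))
  if (any(shp != shp[, 1])) stop("inconsistent page shapes in ", path,
                                 call. = FALSE)
  lapply(pages, function(p) speckleFrame(p * scale, pitch = pitch))
}

#' Write / read a trajectory as delimited text
#'
#' Tab-separated columns: frame, dx_mm, dy_mm, cum_x_mm, cum_y_mm, ref_lag,
#' snr, valid.
#'
#' @param traj A [Trajectory-class].
#' @param path Output path.
#' @return `path` (write) or a [Trajectory-class] (read).
#' @export
writeTrajectory <- function(traj, path) {
  utils::write.table(traj@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectory
#' @param pitchObj Object-plane pitch (mm/px) to attach on read.
#' @export
readTrajectory <- function(path, pitchObj = 1) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  methods::new("Trajectory", table = tab, pitchObj = pitchObj)
}

#' Render a correlation map to PNG
#'
#' Differential maps use a symmetric diverging colormap with zero pinned to
#' the midpoint; auto/cross maps a sequential one.
#'
#' @param map A [CorrelationMap-class].
#' @param path Output PNG path.
#' @param gamma Display gamma for sequential maps.
#' @return `path`, invisibly.
#' @export
writeCorrelationPNG <- function(map, path, gamma = 0.5) {
  v <- map@values
  if (map@kind == "differential") {
    m <- max(abs(v), 1e-300)
    x <- (v / m + 1) / 2
    ramp <- grDevices::colorRamp(c("#2166ac", "#f7f7f7", "#b2182b"))
  } else {
    x <- pmax(v, 0) / max(v, 1e-300)
    x <- x^gamma
    ramp <- grDevices::colorRamp(c("black", "#a0b030", "white"))
  }
  rgb <- ramp(as.numeric(x)) / 255
  arr <- array(rgb, c(dim(v), 3))
  png::writePNG(arr, path)
  invisible(path)
}

#' Render a speckle frame to PNG
#' @param frame A [SpeckleFrame-class].
#' @param path Output PNG path.
#' @param gamma Display gamma.
#' @return `path`, invisibly.
#' @export
writeFramePNG <- function(frame, path, gamma = 0.7) {
  v <- frame@intensity
  x <- (v / max(v, 1e-300))^gamma
  png::writePNG(x, path)
  invisible(path)
}
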